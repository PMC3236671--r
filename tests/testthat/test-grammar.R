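# Lexer and parser behaviour: token stream shape, quoted-string EOL rule,
# text fields, recovery semantics and mode contracts.

test_that("tokenizer produces the expected token stream", {
  tk <- tokenizeCif("")$tokens
  expect_identical(tk$kind, "EOF")
  expect_identical(nrow(tokenizeCif("")$diagnostics), 0L)

  tk <- tokenizeCif("data_x\n_a 1\n")$tokens
  expect_identical(tk$kind, c("DATA_HEADING", "TAG", "VALUE_UNQUOTED", "EOF"))
  expect_identical(tk$text[1:3], c("data_x", "_a", "1"))
  expect_identical(tk$line[1:3], c(1L, 2L, 2L))
  expect_identical(tk$column[1:3], c(1L, 1L, 4L))
})

test_that("token offsets increase and raw spans match the source", {
  src <- "data_x\n_a 'v 1' # note\n_b ;x\nloop_\n_c\n1\n"
  res <- tokenizeCif(src, cifParseOptions(keepComments = TRUE))
  tk <- res$tokens
  expect_true(all(diff(tk$offset) > 0))
  for (i in seq_len(nrow(tk) - 1L)) {
    span <- substr(src, tk$offset[i] + 1L, tk$offset[i] + nchar(tk$text[i]))
    expect_identical(span, tk$text[i])
  }
})

test_that("quoted strings cannot cross an end of line; recovery closes at EOL", {
  res <- tokenizeCif("data_x\n_a 'abc\n")
  d <- res$diagnostics
  expect_identical(d$class, 1L)
  expect_true(d$recovered)
  v <- res$tokens[res$tokens$kind == "VALUE_SQUOTED", ]
  expect_identical(v$value, "abc")

  # with whitespace inside the unterminated string the class is 2
  d2 <- tokenizeCif("data_x\n_a 'two words\n")$diagnostics
  expect_identical(d2$class, 2L)

  # a quote followed by non-whitespace does not terminate the string
  tk <- tokenizeCif("data_x\n_a 'it's fine'\n")$tokens
  expect_identical(tk$value[tk$kind == "VALUE_SQUOTED"], "it's fine")
})

test_that("semicolon text fields parse and an unterminated one is fatal", {
  doc <- parseCif("data_x\n_a\n;\nline1\nline2\n;\n")
  expect_identical(cifItem(doc[["x"]], "_a"), "line1\nline2")

  res <- tokenizeCif("data_x\n_a ;no close\n")
  expect_identical(res$tokens$kind[length(res$tokens$kind)], "EOF")
  # ';' mid-line is an ordinary character, not a field delimiter
  expect_identical(res$tokens$value[3], ";no")

  res2 <- tokenizeCif("data_x\n_a\n;\nnever closed\n")
  d <- res2$diagnostics
  expect_identical(d$class, 4L)
  expect_false(d$recovered)
  # everything parsed before the failure is surfaced
  doc2 <- parseCif("data_x\n_before 7\n_a\n;\nnever closed\n")
  expect_identical(cifItem(doc2[["x"]], "_before"), "7")
  expect_true(4L %in% cifDiagnostics(doc2)$class)
})

test_that("non-ASCII bytes yield class 9 and the pair is dropped", {
  txt <- "data_x\n_name 'Jos\xe9'\n_b 2\n"
  Encoding(txt) <- "latin1"
  doc <- parseCif(txt)
  d <- cifDiagnostics(doc)
  expect_true(9L %in% d$class)
  expect_false(hasCifItem(doc[["x"]], "_name"))
  expect_identical(cifItem(doc[["x"]], "_b"), "2")
})

test_that("lenient recovery yields the documented partial model", {
  # class 5: first value kept, extras discarded
  doc <- parseCif("data_x\n_a 1 2\n_b 3\n")
  expect_identical(cifItem(doc[["x"]], "_a"), "1")
  expect_identical(cifItem(doc[["x"]], "_b"), "3")
  # class 6: valueless tag dropped
  doc <- parseCif("data_x\n_a\n_b 2\n")
  expect_false(hasCifItem(doc[["x"]], "_a"))
  expect_identical(cifItem(doc[["x"]], "_b"), "2")
  # class 7: synthetic block with empty name
  doc <- parseCif("_a 1\n_b 2\n")
  expect_identical(names(doc), "")
  expect_identical(cifItem(doc[[""]], "_a"), "1")
  # class 8: heading accepted verbatim
  doc <- parseCif("data_my file\n_a 1\n")
  expect_identical(names(doc), "my file")
  # class 10: offending pair discarded
  doc <- parseCif("data_x\n_a [abc]\n_b 2\n")
  expect_false(hasCifItem(doc[["x"]], "_a"))
  # class 11: the whole loop is rejected, with a loop-scoped diagnostic
  doc <- parseCif("data_a\nloop_\n_x _y\n1 2 3\n")
  expect_length(doc[["a"]]@loops, 0L)
  d <- cifDiagnostics(doc)
  expect_true(11L %in% d$class)
  expect_match(d$message[d$class == 11L], "_x")
  # class 3: junk preamble skipped up to the first heading
  doc <- parseCif("junk line here\ndata_x\n_a 1\n")
  expect_identical(names(doc), "x")
  expect_true(3L %in% cifDiagnostics(doc)$class)
})

test_that("global_ frames are errors unless permitted, then merge as fallback scope", {
  txt <- "global_\n_t 5\ndata_b\n_u 6\n"
  d <- cifDiagnostics(parseCif(txt))
  expect_true(12L %in% d$class[d$severity == "error"])
  doc <- parseCif(txt, cifParseOptions(permitGlobalBlocks = TRUE))
  blk <- doc[["b"]]
  expect_identical(cifItem(blk, "_t"), "5")
  expect_identical(cifItem(blk, "_u"), "6")
  # the global item does not pollute block ownership on write
  expect_false(grepl("_t", writeCif(doc)))
})

test_that("duplicate names and blocks: last wins leniently, strict raises", {
  doc <- parseCif("data_a\n_a 1\ndata_a\n_a 2\n")
  expect_length(doc, 1L)
  expect_identical(cifItem(doc[["a"]], "_a"), "2")
  expectStrictRaises("data_a\n_a 1\ndata_a\n_a 2\n")
  doc <- parseCif("data_a\n_x 1\n_x 2\n")
  expect_identical(cifItem(doc[["a"]], "_x"), "2")
  expectStrictRaises("data_a\n_x 1\n_x 2\n")
})

test_that("strict mode raises a classified condition with the diagnostic attached", {
  err <- tryCatch(parseCif("data_x\n_a [bad]\n", cifParseOptions(strict = TRUE)),
                  error = identity)
  expect_s3_class(err, "cifSyntaxError")
  expect_identical(err$diagnostic$class, 10L)
  expect_identical(err$diagnostic$line, 2L)
})

test_that("a strictly parsed document implies zero error diagnostics", {
  txt <- makeRandomDocument(seed = 11, nItems = 6, nLoops = 2)$text
  doc <- parseCif(txt, cifParseOptions(strict = TRUE))
  d <- cifDiagnostics(doc)
  expect_identical(sum(d$severity == "error"), 0L)
})

test_that("parsing is deterministic", {
  txt <- makeMalformed(5)$text
  a <- parseCif(txt); b <- parseCif(txt)
  expect_true(cifIdentical(a, b))
  expect_identical(cifDiagnostics(a), cifDiagnostics(b))
})

test_that("classifyCifError maps contexts to the numbered taxonomy", {
  expect_identical(classifyCifError(list(state = "value_position",
                                         text = "[abc]")), 10L)
  x <- "caf\xe9"; Encoding(x) <- "latin1"
  expect_identical(classifyCifError(list(text = x)), 9L)
  expect_identical(classifyCifError(list(text = "GLOBAL_")), 12L)
  expect_identical(classifyCifError(list(state = "loop_count")), 11L)
  expect_identical(classifyCifError(list(text = "benign")), 0L)
})

test_that("reserved words in value position are warned and kept as strings", {
  doc <- parseCif("data_x\n_a stop_\n_b 1\n")
  expect_identical(cifItem(doc[["x"]], "_b"), "1")
  d <- cifDiagnostics(doc)
  expect_true(any(d$severity == "warning"))
})

test_that("overlong lines warn but never error", {
  txt <- paste0("data_x\n_a ", strrep("y", 3000), "\n")
  doc <- parseCif(txt, cifParseOptions(strict = TRUE))  # must not raise
  d <- cifDiagnostics(doc)
  expect_true(any(d$severity == "warning" & d$class == 0L))
})
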