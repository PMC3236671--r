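# Dictionary loading (DDL1/DDL2) and document validation through the
# replaceable error handler.

test_that("the toy DDL1 dictionary loads with six definitions", {
  dict <- loadDictionary(toyDdl1Dictionary())
  expect_s4_class(dict, "CifDictionary")
  expect_identical(dict@ddlVersion, "ddl1")
  expect_identical(length(dict), 6L)
  def <- dictDefinition(dict, "_TOY_COUNT")
  expect_identical(def$dataType, "numb")
  expect_equal(def$range, c(0, NA))
  expect_identical(dictDefinition(dict, "_toy_site_label")$listContext,
                   "must_loop")
  expect_true(dictDefinition(dict, "_toy_length")$suAllowed)
  expect_false(dictDefinition(dict, "_toy_count")$suAllowed)
  expect_identical(dictDefinition(dict, "_toy_site_occupancy")$linkedParent,
                   "_toy_site_label")
})

test_that("the toy DDL2 dictionary loads from save frames", {
  dict <- loadDictionary(toyDdl2Dictionary())
  expect_identical(dict@ddlVersion, "ddl2")
  expect_identical(length(dict), 4L)
  expect_identical(dictDefinition(dict, "_toy.count")$dataType, "numb")
  expect_identical(dictDefinition(dict, "_toy.site_occupancy")$linkedParent,
                   "_toy.site_id")
  # regex type codes come from the dictionary's own type list
  expect_false(is.na(dictDefinition(dict, "_toy.color")$typeRegex))
})

test_that("dictionary sources resolve or fail clearly", {
  tmp <- tempfile(fileext = ".dic")
  writeLines(toyDdl1Dictionary(), tmp, sep = "")
  dict <- loadDictionary(tmp)
  expect_identical(length(dict), 6L)
  expect_error(loadDictionary("/nonexistent/path.dic"), "cannot resolve")
  # a register key resolves through the pluggable resolver
  withr::local_options(cifio.dictionaryResolver = function(key) {
    if (key == "toy_core") tmp else stop("unknown key")
  })
  expect_identical(length(loadDictionary("toy_core")), 6L)
  expect_error(loadDictionary("data_x\n_a 1\n"), "zero definitions")
})

test_that("self-validation: toy dictionaries parse with zero error diagnostics", {
  for (txt in c(toyDdl1Dictionary(), toyDdl2Dictionary())) {
    doc <- parseCif(txt, cifParseOptions(permitGlobalBlocks = TRUE))
    d <- cifDiagnostics(doc)
    expect_identical(sum(d$severity == "error"), 0L)
  }
})

test_that("each seeded violation type is detected exactly once", {
  dict <- loadDictionary(toyDdl1Dictionary())
  # one violation per category: type, enumeration, range, su, list-context
  # (both directions), missing parent
  doc <- parseCif(paste0(
    "data_bad\n",
    "_toy_count notanumber\n",          # type
    "_toy_color blue\n",                # enumeration
    "_toy_name .\n",                    # inapplicable: always accepted
    "loop_\n_toy_site_occupancy\n1.2\n" # range + missing parent
  ))
  rep <- validateCif(doc, dict)
  f <- rep@findings
  expect_identical(sum(f$code == "type"), 1L)
  expect_identical(sum(f$code == "enumeration"), 1L)
  expect_identical(sum(f$code == "range"), 1L)
  expect_identical(sum(f$code == "missing_parent"), 1L)
  expect_identical(rep@nErrors, 4L)
  expect_identical(rep@nWarnings, 0L)

  # su where forbidden
  rep2 <- validateCif(parseCif("data_b\n_toy_count 3(1)\n"), dict)
  expect_identical(sum(rep2@findings$code == "su_not_allowed"), 1L)
  # su where allowed
  rep3 <- validateCif(parseCif("data_b\n_toy_length 3.2(1)\n"), dict)
  expect_identical(rep3@nErrors, 0L)
  # list context, both directions
  rep4 <- validateCif(parseCif("data_b\n_toy_site_label x\n"), dict)
  expect_identical(sum(rep4@findings$code == "list_context"), 1L)
  rep5 <- validateCif(parseCif("data_b\nloop_\n_toy_name\na\n"), dict)
  expect_identical(sum(rep5@findings$code == "list_context"), 1L)
  # clean content yields no findings
  rep6 <- validateCif(parseCif(
    "data_ok\n_toy_count 4\n_toy_color red\nloop_\n_toy_site_label\n_toy_site_occupancy\nA1 0.5\n"),
    dict)
  expect_identical(nrow(rep6@findings), 0L)
})

test_that("unknown names warn; adding one never decreases the finding count", {
  dict <- loadDictionary(toyDdl1Dictionary())
  doc1 <- parseCif("data_b\n_toy_count 1\n")
  doc2 <- parseCif("data_b\n_toy_count 1\n_undefined_thing 2\n")
  r1 <- validateCif(doc1, dict)
  r2 <- validateCif(doc2, dict)
  expect_identical(r2@findings$severity[r2@findings$code == "unknown_name"],
                   "warning")
  expect_gte(nrow(r2@findings), nrow(r1@findings))
})

test_that("DDL2 validation applies int/float/regex type codes", {
  dict <- loadDictionary(toyDdl2Dictionary())
  rep <- validateCif(parseCif("data_b\n_toy.count 3.5\n"), dict)
  # 3.5 is a number, numb accepts it; the stricter int regex is attached to
  # the definition but numb typing wins -- range check still applies
  expect_identical(sum(rep@findings$code == "range"), 0L)
  rep2 <- validateCif(parseCif("data_b\n_toy.count -1\n"), dict)
  expect_identical(sum(rep2@findings$code == "range"), 1L)
  rep3 <- validateCif(parseCif("data_b\n_toy.color 'two words'\n"), dict)
  expect_identical(sum(rep3@findings$code == "type"), 1L)
})

test_that("every finding is routed through the handler before inclusion", {
  dict <- loadDictionary(toyDdl1Dictionary())
  doc <- parseCif(paste0("data_bad\n_toy_count -5\n_toy_color mauve\n",
                         "_unknown 1\n"))
  seen <- 0L
  rep <- validateCif(doc, dict, handler = function(f) seen <<- seen + 1L)
  expect_identical(seen, nrow(rep@findings))
  expect_gte(seen, 3L)
  # a handler may escalate a finding to an exception (it decides continuation)
  expect_error(
    validateCif(doc, dict, handler = function(f)
      if (f$severity == "error") stop("escalated: ", f$message)),
    "escalated")
})
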