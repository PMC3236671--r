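# Object model: lookup, loop-name inference, loop construction, row
# iteration, numeric convention and editing semantics.

test_that("item lookup is case-insensitive and errors on absent names", {
  blk <- cifBlock("b", list("_cell_length_a" = "10.0"))
  expect_identical(cifItem(blk, "_CELL_LENGTH_A"), "10.0")
  blk <- addLoop(blk, c("_x", "_y"), list(c("1", "2"), c("3", "4")))
  expect_identical(cifItem(blk, "_y"), c("2", "4"))
  expect_error(cifItem(blk, "_absent"), "_absent")
  expect_error(cifItem(blk, "_absent"), "'b'")   # error names the block
})

test_that("loop-name inference matches the brute-force oracle", {
  expect_identical(
    inferLoopName(c("_atom_site_label", "_atom_site_fract_x",
                    "_atom_site_fract_y"), "ddl1"),
    "_atom_site")
  expect_identical(
    inferLoopName(c("_atom_site.id", "_atom_site.type_symbol"), "ddl2"),
    "_atom_site")
  expect_identical(inferLoopName("_only", "ddl1"), "_only")
  # no separator reached beyond the leading underscore -> first name whole
  expect_identical(inferLoopName(c("_abc", "_abd"), "ddl1"), "_abc")

  set.seed(42)
  words <- function() paste(sample(letters[1:4], sample(2:5, 1),
                                   replace = TRUE), collapse = "")
  for (i in 1:200) {
    sep <- sample(c("_", "."), 1)
    dialect <- if (sep == "_") "ddl1" else "ddl2"
    nn <- sample(1:5, 1)
    nms <- vapply(seq_len(nn), function(j)
      paste0("_", paste(replicate(sample(1:4, 1), words()), collapse = sep)),
      character(1))
    expect_identical(inferLoopName(nms, dialect), lcpOracle(nms, sep),
                     info = paste(nms, collapse = " "))
  }
})

test_that("addLoop validates shape and uniqueness", {
  blk <- cifBlock("b")
  blk <- addLoop(blk, c("_a", "_b"), list(c(1, 2), c(3, 4)))
  expect_identical(loopNrow(cifLoop(blk, "_a")), 2L)
  expect_error(addLoop(cifBlock("b"), c("_a", "_b"), list(c(1, 2), 3)),
               "exact multiple|loop-shape")
  expect_error(addLoop(blk, "_a", list("9")), "already present")
})

test_that("row iteration round-trips through column storage", {
  blk <- addLoop(cifBlock("b"), c("_p_x", "_p_y"),
                 list(c("1", "2"), c("3", "4")))
  lp <- cifLoop(blk, "_p")
  rows <- loopRows(lp)
  expect_length(rows, 2L)
  expect_identical(rows[[1]], c("_p_x" = "1", "_p_y" = "2"))
  # empty loop iterates to an empty list
  empty <- new("CifLoop", names = "_q", columns = list("_q" = character(0)),
               name = "_q")
  expect_identical(loopRows(empty), list())
  # property: rows -> addLoop -> loopRows is the identity
  set.seed(7)
  for (i in 1:25) {
    nc <- sample(1:4, 1); nr <- sample(0:5, 1)
    nms <- paste0("_t_", letters[seq_len(nc)])
    rws <- lapply(seq_len(nr), function(r)
      as.character(sample(100, nc)))
    lp <- cifLoop(addLoop(cifBlock("b"), nms, rws), nms[1])
    got <- lapply(loopRows(lp), unname)
    expect_identical(got, rws)
  }
})

test_that("the CIF numeric convention is interpreted correctly", {
  expect_identical(parseCifNumber("?")$semantic, "unknown")
  expect_identical(parseCifNumber(".")$semantic, "inapplicable")
  v <- parseCifNumber("12.34(5)")
  expect_equal(v$number, 12.34)
  expect_equal(v$su, 0.05)
  v <- parseCifNumber("-1.2e1")
  expect_equal(v$number, -12)
  expect_true(is.na(v$su))
  expect_identical(parseCifNumber("abc")$semantic, "string")
  expect_identical(parseCifNumber("12.3.4")$semantic, "string")
  v <- parseCifNumber("25(3)")
  expect_equal(v$su, 3)

  # property vs the string-arithmetic oracle
  set.seed(13)
  for (i in 1:200) {
    val <- round(stats::runif(1, -100, 100), sample(0:6, 1))
    dig <- sample(1:99, 1)
    dec <- sample(0:6, 1)
    s <- paste0(formatC(val, format = "f", digits = dec), "(", dig, ")")
    got <- parseCifNumber(s)
    expect_identical(got$semantic, "number")
    expect_equal(got$su, suOracle(s), tolerance = 1e-12, info = s)
    expect_equal(got$number, as.numeric(formatC(val, format = "f",
                                                digits = dec)), info = s)
  }
})

test_that("formatNumberSu round-trips value and uncertainty", {
  expect_identical(formatNumberSu(10.232, 0.003), "10.232(3)")
  expect_identical(formatNumberSu(1.5, NA), "1.5")
  expect_identical(formatNumberSu(25, 3), "25(3)")
  set.seed(5)
  for (i in 1:100) {
    val <- round(stats::runif(1), 4)
    su <- sample(1:9, 1) * 1e-4
    s <- formatNumberSu(val, su)
    back <- parseCifNumber(s)
    expect_equal(back$number, val)
    expect_equal(back$su, su)
  }
})

test_that("editing keeps the one-value-per-name invariant", {
  blk <- cifBlock("b", list("_a" = "1"))
  blk <- setCifItem(blk, "_a", "2")
  expect_identical(cifItem(blk, "_a"), "2")
  expect_length(blk@items, 1L)
  # setting over a loop column removes the column
  blk <- addLoop(blk, c("_c_x", "_c_y"), list(c("1", "2")))
  blk <- setCifItem(blk, "_c_x", "9")
  expect_identical(cifItem(blk, "_c_x"), "9")
  expect_identical(cifLoop(blk, "_c_y")@names, "_c_y")
  # removing the last column removes the loop
  blk <- removeCifItem(blk, "_c_y")
  expect_null(cifLoop(blk, "_c_y"))
  expect_error(removeCifItem(blk, "_gone"), "not found")
})

test_that("document accessors index blocks case-insensitively", {
  doc <- parseCif("data_First\n_a 1\ndata_second\n_b 2\n")
  expect_identical(length(doc), 2L)
  expect_identical(names(doc), c("First", "second"))
  expect_identical(cifItem(doc[["FIRST"]], "_a"), "1")
  expect_identical(doc[["second"]][["_b"]], "2")
})
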