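# Crystallographic bridge: symmetry operations, extraction/emission round
# trips, reflection handling and metric-tensor geometry with su propagation.

test_that("xyz triplets parse and render canonically, round-tripping", {
  id <- parseSymOp("x,y,z")
  expect_equal(id@rotation, diag(3))
  inv <- parseSymOp("-x,-y,-z")
  expect_equal(inv@rotation, -diag(3))
  screw <- parseSymOp("-x, y+1/2, -z+1/2")
  expect_equal(screw@translation, c(0, 0.5, 0.5))
  expect_identical(symOpXyz(screw), "-x,y+1/2,-z+1/2")
  # decimals and leading fractions are understood
  expect_true(symOpEqual(parseSymOp("1/2+x,-y,0.5+z"),
                         parseSymOp("x+1/2,-y,z+1/2")))
  expect_error(parseSymOp("x,y"), "unparseable")
  expect_error(parseSymOp("x,y,w"), "unparseable")
  # round trip for all ops of every bundled group
  for (g in spaceGroupNames())
    for (op in spaceGroupSymops(g))
      expect_true(symOpEqual(parseSymOp(symOpXyz(op)), op))
})

test_that("group closure matches the brute-force 4x4-matrix oracle", {
  expected <- c("P1" = 1L, "P-1" = 2L, "P2_1/c" = 4L)
  for (g in names(expected)) {
    ops <- spaceGroupSymops(g)
    expect_length(ops, expected[[g]])
    expect_identical(closureSize4x4(lapply(ops, mat4)),
                     as.integer(expected[[g]]))
    expect_true(symOpsClosed(ops))
  }
  # a 2_1 screw alone generates a closed group of order 2
  screw <- parseSymOp("-x,y+1/2,-z+1/2")
  expect_length(symOpClosure(list(screw)), 2L)
  # screw + inversion generate the full 4-op group
  expect_length(symOpClosure(list(screw, parseSymOp("-x,-y,-z"))), 4L)
})

test_that("symmetryOpsAsLoop emits closed sets and rejects non-closed ones", {
  lp <- symmetryOpsAsLoop(list(symOp()), "ddl1")
  expect_identical(loopNrow(lp), 1L)
  expect_identical(lp@columns[["_symmetry_equiv_pos_as_xyz"]], "x,y,z")
  lp2 <- symmetryOpsAsLoop(spaceGroupSymops("P-1"), "ddl1")
  expect_identical(loopNrow(lp2), 2L)
  lp4 <- symmetryOpsAsLoop(spaceGroupSymops("P2_1/c"), "ddl2")
  expect_identical(loopNrow(lp4), 4L)
  expect_identical(lp4@names[2], "_space_group_symop.operation_xyz")
  # identity always leads
  expect_identical(lp4@columns[[2]][1], "x,y,z")
  # {identity, screw, inversion} is NOT closed (closure has 4 elements)
  bad <- list(symOp(), parseSymOp("-x,y+1/2,-z+1/2"), parseSymOp("-x,-y,-z"))
  expect_error(symmetryOpsAsLoop(bad, "ddl1"), "closure")
})

test_that("crystal symmetry extraction reads cell, symops and su", {
  blk <- cifBlock("c", list(
    "_cell_length_a" = "10.0", "_cell_length_b" = "10.0",
    "_cell_length_c" = "10.0", "_cell_angle_alpha" = "90",
    "_cell_angle_beta" = "90", "_cell_angle_gamma" = "90"))
  expect_warning(extractCrystalSymmetry(blk), "identity")
  sym <- suppressWarnings(extractCrystalSymmetry(blk))
  expect_equal(sym$cell@a, 10)
  expect_length(sym$symops, 1L)

  blk2 <- addLoop(blk, "_symmetry_equiv_pos_as_xyz", list("x,y,z", "-x,-y,-z"))
  sym2 <- extractCrystalSymmetry(blk2)
  expect_length(sym2$symops, 2L)
  expect_equal(sym2$symops[[2]]@rotation, -diag(3))

  blk3 <- setCifItem(blk, "_cell_length_a", "10.232(3)")
  blk3 <- setCifItem(blk3, "_symmetry_space_group_name_H-M", "P -1")
  sym3 <- extractCrystalSymmetry(blk3)
  expect_equal(sym3$cell@a, 10.232)
  expect_equal(sym3$cell@su[1], 0.003)
  expect_length(sym3$symops, 2L)   # symbol resolved via the bundled table

  expect_error(extractCrystalSymmetry(cifBlock("e")), "missing cell item")
  blk4 <- setCifItem(blk, "_cell_length_a", "abc")
  expect_error(extractCrystalSymmetry(blk4), "non-numeric")
})

test_that("structure emit/extract is the identity on the numeric content", {
  for (s in 1:10) {
    grp <- c("P1", "P-1", "P2_1/c")[1 + s %% 3]
    st <- makeStructureFixture(grp, nSites = 3 + s %% 4, seed = s,
                               aniso = s %% 2 == 0)
    txt <- writeCif(cifDocument(list(structureAsCif(st))))
    doc <- parseCif(txt, cifParseOptions(strict = TRUE))
    st2 <- extractCrystalStructure(doc[["structure"]])
    expect_equal(metricTensor(st2@cell), metricTensor(st@cell))
    expect_equal(st2@cell@su, st@cell@su)
    expect_identical(st2@sites$label, st@sites$label)
    for (col in c("x", "y", "z", "occ", "uiso", "suX", "suY", "suZ",
                  "u11", "u23", "suU11"))
      expect_equal(st2@sites[[col]], st@sites[[col]], info = paste(s, col))
    # symop sets match as sets
    expect_length(st2@symops, length(st@symops))
    for (op in st@symops)
      expect_true(any(vapply(st2@symops, symOpEqual, logical(1), op)))
  }
})

test_that("mmCIF-pointed names are understood on both sides", {
  st <- makeStructureFixture("P-1", nSites = 2, seed = 3)
  txt <- writeCif(cifDocument(list(structureAsCif(st, dialect = "ddl2"))))
  expect_match(txt, "_atom_site.fract_x", fixed = TRUE)
  doc <- parseCif(txt, cifParseOptions(strict = TRUE))
  st2 <- extractCrystalStructure(doc[["structure"]])
  expect_equal(st2@sites$x, st@sites$x)
  expect_length(st2@symops, 2L)
})

test_that("reflection extraction handles '?', bad indices and round trips", {
  blk <- addLoop(cifBlock("r"),
                 c("_refln_index_h", "_refln_index_k", "_refln_index_l",
                   "_refln_F_squared_meas", "_refln_F_squared_sigma"),
                 list(c("1", "0", "0", "25.1", "0.4"),
                      c("0", "1", "0", "?", "0.5")))
  rs <- extractReflections(blk)
  expect_identical(nrow(rs@indices), 2L)
  expect_equal(rs@data$F_squared_meas, c(25.1, NA))
  expect_equal(rs@sigmas$F_squared_meas, c(0.4, 0.5))

  # indices-only loop: empty data with a warning
  blk2 <- addLoop(cifBlock("r2"),
                  c("_refln_index_h", "_refln_index_k", "_refln_index_l"),
                  list(c("1", "0", "0")))
  expect_warning(rs2 <- extractReflections(blk2), "no recognized")
  expect_length(rs2@data, 0L)

  # non-integer and (0,0,0) rows are dropped with warnings
  blk3 <- addLoop(cifBlock("r3"),
                  c("_refln_index_h", "_refln_index_k", "_refln_index_l",
                    "_refln_F_meas"),
                  list(c("1", "0", "0", "5"), c("x", "0", "0", "6"),
                       c("0", "0", "0", "7")))
  ws <- capture_warnings(rs3 <- extractReflections(blk3))
  expect_length(ws, 2L)
  expect_identical(nrow(rs3@indices), 1L)
  expect_equal(rs3@data$F_meas, 5)

  expect_error(extractReflections(cifBlock("e")), "no _refln index")

  # generator fixture round trip including missing values
  rs4 <- makeReflectionFixture(n = 100, seed = 9)
  doc <- parseCif(writeCif(cifDocument(list(reflectionsAsCif(rs4)))),
                  cifParseOptions(strict = TRUE))
  rs5 <- extractReflections(doc[["reflections"]])
  expect_identical(unname(rs5@indices), unname(rs4@indices))
  expect_equal(rs5@data, rs4@data)
  expect_equal(rs5@sigmas, rs4@sigmas)
})

test_that("metric-tensor geometry matches the Cartesian oracle", {
  st <- crystalStructure(unitCell(10, 10, 10),
    sites = data.frame(label = c("A", "B", "C"), symbol = "C",
                       x = c(0, 0.5, 0), y = c(0, 0, 0.5), z = 0))
  expect_equal(siteDistance(st, 1, 2)$value, 5)
  expect_equal(siteAngle(st, 2, 1, 3)$value, 90)
  expect_error(siteDistance(st, 1, 1), "coincident")
  expect_error(siteAngle(st, 1, 1, 2), "undefined angle")

  set.seed(31)
  for (i in 1:100) {
    cell <- unitCell(runif(1, 4, 12), runif(1, 4, 12), runif(1, 4, 12),
                     runif(1, 75, 105), runif(1, 75, 105), runif(1, 75, 105))
    x <- matrix(runif(9), 3, 3)
    stx <- crystalStructure(cell, sites = data.frame(
      label = c("A", "B", "C"), symbol = "C",
      x = x[, 1], y = x[, 2], z = x[, 3]))
    expect_equal(siteDistance(stx, 1, 2)$value,
                 cartDistance(cell, x[1, ], x[2, ]), tolerance = 1e-12)
    expect_equal(siteAngle(stx, 1, 2, 3)$value,
                 cartAngle(cell, x[1, ], x[2, ], x[3, ]), tolerance = 1e-10)
  }
})

test_that("analytic su propagation matches finite differences", {
  set.seed(17)
  for (i in 1:10) {
    cell <- unitCell(runif(1, 4, 12), runif(1, 4, 12), runif(1, 4, 12),
                     runif(1, 80, 100), runif(1, 80, 100), runif(1, 80, 100),
                     su = c(runif(3, 1e-4, 1e-3), runif(3, 1e-3, 1e-2)))
    x <- matrix(runif(9), 3, 3)
    st <- crystalStructure(cell, sites = data.frame(
      label = c("A", "B", "C"), symbol = "C",
      x = x[, 1], y = x[, 2], z = x[, 3]))
    # distance: gradient over (site1, site2) coordinates and cell parameters
    A <- matrix(rnorm(36, sd = 1e-3), 6)
    cov6 <- crossprod(A)
    got <- siteDistance(st, 1, 2, covariance = cov6)
    dfun <- function(p) {
      cl <- unitCell(p[7], p[8], p[9], p[10], p[11], p[12])
      cartDistance(cl, p[1:3], p[4:6])
    }
    p0 <- c(x[1, ], x[2, ], cell@a, cell@b, cell@c, cell@alpha, cell@beta,
            cell@gamma)
    g <- fdGrad(dfun, p0)
    expected <- sqrt(as.numeric(t(g[1:6]) %*% cov6 %*% g[1:6]) +
                     sum((g[7:12] * cell@su)^2))
    expect_equal(got$su, expected, tolerance = 1e-6)
    # angle
    A9 <- matrix(rnorm(81, sd = 1e-3), 9)
    cov9 <- crossprod(A9)
    gota <- siteAngle(st, 1, 2, 3, covariance = cov9)
    afun <- function(p) {
      cl <- unitCell(p[10], p[11], p[12], p[13], p[14], p[15])
      cartAngle(cl, p[1:3], p[4:6], p[7:9])
    }
    pa <- c(x[1, ], x[2, ], x[3, ], cell@a, cell@b, cell@c, cell@alpha,
            cell@beta, cell@gamma)
    ga <- fdGrad(afun, pa)
    expecteda <- sqrt(as.numeric(t(ga[1:9]) %*% cov9 %*% ga[1:9]) +
                      sum((ga[10:15] * cell@su)^2))
    expect_equal(gota$su, expecteda, tolerance = 1e-5)
  }
})

test_that("geometryTable extracts per-element covariance submatrices", {
  st <- makeStructureFixture("P1", nSites = 3, seed = 4)
  n <- 3L
  A <- matrix(rnorm((3 * n)^2, sd = 1e-3), 3 * n)
  cov <- crossprod(A)
  tab <- geometryTable(st, pairs = rbind(c(1, 2), c(2, 3)),
                       triples = rbind(c(1, 2, 3)), covariance = cov)
  expect_identical(tab$kind, c("distance", "distance", "angle"))
  expect_true(all(is.finite(tab$value)))
  expect_true(all(tab$su > 0))
  d12 <- siteDistance(st, 1, 2, covariance = cov[1:6, 1:6])
  expect_equal(tab$value[1], d12$value)
  expect_equal(tab$su[1], d12$su)
})
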