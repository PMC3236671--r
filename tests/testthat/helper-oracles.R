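# Independent oracles used by the dual-route checks. Each deliberately
# takes a different computational path from the package implementation.

# longest common prefix + separator trim, char-by-char brute force
lcpOracle <- function(names, sep) {
  pfx <- strsplit(names[1], "")[[1]]
  for (nm in names[-1]) {
    ch <- strsplit(nm, "")[[1]]
    k <- 0
    while (k < min(length(pfx), length(ch)) && pfx[k + 1] == ch[k + 1])
      k <- k + 1
    pfx <- pfx[seq_len(k)]
  }
  pos <- which(pfx == sep)
  pos <- pos[pos >= 2]
  if (!length(pos)) return(names[1])
  paste(pfx[seq_len(max(pos) - 1)], collapse = "")
}

# string-based su arithmetic: count decimals textually, build the scale
# factor as a string ("0.001") rather than via 10^-k
suOracle <- function(valueStr) {
  m <- regmatches(valueStr, regexec("^([^()]*)\\(([0-9]+)\\)$", valueStr))[[1]]
  if (length(m) == 0) return(NA_real_)
  mant <- m[2]; dig <- m[3]
  frac <- sub("^[^.]*\\.?", "", sub("[eE].*$", "", mant))
  scale <- if (nchar(frac) == 0) "1" else
    paste0("0.", strrep("0", nchar(frac) - 1), "1")
  expo <- regmatches(mant, regexec("[eE]([+-]?[0-9]+)", mant))[[1]]
  s <- as.numeric(dig) * as.numeric(scale)
  if (length(expo)) s <- s * 10^as.numeric(expo[2])
  s
}

# Cartesian route: build explicit basis vectors and use plain Euclidean
# geometry (independent of the metric-tensor path)
cellBasis <- function(a, b, cc, al, be, ga) {
  d2r <- pi / 180
  ca <- cos(al * d2r); cb <- cos(be * d2r); cg <- cos(ga * d2r)
  sg <- sin(ga * d2r)
  va <- c(a, 0, 0)
  vb <- c(b * cg, b * sg, 0)
  cz <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg) / sg
  vc <- c(cc * cb, cc * (ca - cb * cg) / sg, cc * cz)
  rbind(va, vb, vc)
}

cartDistance <- function(cell, x1, x2) {
  B <- cellBasis(cell@a, cell@b, cell@c, cell@alpha, cell@beta, cell@gamma)
  v <- as.numeric(t(B) %*% (x2 - x1))
  sqrt(sum(v^2))
}

cartAngle <- function(cell, xi, xj, xk) {
  B <- cellBasis(cell@a, cell@b, cell@c, cell@alpha, cell@beta, cell@gamma)
  u <- as.numeric(t(B) %*% (xi - xj))
  v <- as.numeric(t(B) %*% (xk - xj))
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# 4x4 augmented-matrix group closure, independent of the SymOp class
mat4 <- function(op) {
  m <- diag(4)
  m[1:3, 1:3] <- op@rotation
  m[1:3, 4] <- op@translation
  m
}
closureSize4x4 <- function(genMats, cap = 100) {
  norm1 <- function(m) { m[1:3, 4] <- round(m[1:3, 4] * 12) %% 12 / 12; m }
  key <- function(m) paste(round(m * 12), collapse = ",")
  seen <- new.env()
  frontier <- c(list(diag(4)), lapply(genMats, norm1))
  for (m in frontier) assign(key(norm1(m)), norm1(m), envir = seen)
  repeat {
    added <- FALSE
    mats <- as.list(seen)
    for (a in mats) for (b in mats) {
      p <- norm1(a %*% b)
      if (!exists(key(p), envir = seen)) {
        assign(key(p), p, envir = seen)
        added <- TRUE
      }
      if (length(ls(seen)) > cap) stop("no closure")
    }
    if (!added) break
  }
  length(ls(seen))
}

# central finite-difference gradient of f at p
fdGrad <- function(f, p, h = 1e-6) {
  vapply(seq_along(p), function(i) {
    e <- numeric(length(p)); e[i] <- h
    (f(p + e) - f(p - e)) / (2 * h)
  }, numeric(1))
}

expectStrictRaises <- function(text) {
  expect_error(parseCif(text, cifParseOptions(strict = TRUE)),
               class = "cifSyntaxError")
}
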