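## Metric-tensor geometry: interatomic distances and angles directly from
## fractional coordinates, d = sqrt(dx' G dx), with optional first-order
## propagation of standard uncertainties. The covariance over the involved
## fractional coordinates is sandwiched with the analytic gradient; the six
## cell parameters contribute independently through their su values
## (cross-correlation between coordinates and cell is not modelled).

.suFromGradients <- function(gradFrac, covariance, gradCell, cellSu) {
  v <- 0
  if (!is.null(covariance)) {
    stopifnot(is.matrix(covariance),
              nrow(covariance) == length(gradFrac),
              ncol(covariance) == length(gradFrac))
    v <- v + as.numeric(t(gradFrac) %*% covariance %*% gradFrac)
  }
  ok <- !is.na(cellSu)
  if (any(ok)) v <- v + sum((gradCell[ok] * cellSu[ok])^2)
  if (v < 0 && v > -1e-16) v <- 0
  sqrt(v)
}

#' Interatomic distance from fractional coordinates
#'
#' `d = sqrt(dx' G dx)` with `G` the metric tensor of the structure's cell.
#' With a covariance matrix over the six fractional coordinates (site i
#' first, then site j) the standard uncertainty is computed by first-order
#' propagation; standard uncertainties on the cell parameters (the cell's
#' `su` slot) contribute independently.
#'
#' @param structure a [CrystalStructure-class].
#' @param i,j site indices (row numbers in `structure@sites`).
#' @param covariance optional 6x6 symmetric positive-semidefinite matrix
#'   over (xi, yi, zi, xj, yj, zj), in fractional units squared.
#' @return list with `value` (Angstrom) and `su` (Angstrom, `NA` when no
#'   uncertainty source is given).
#' @examples
#' st <- crystalStructure(unitCell(10, 10, 10),
#'   sites = data.frame(label = c("A", "B"), symbol = "C",
#'                      x = c(0, 0.5), y = 0, z = 0))
#' siteDistance(st, 1, 2)$value   # 5
#' @export
siteDistance <- function(structure, i, j, covariance = NULL) {
  G <- metricTensor(structure@cell)
  s <- structure@sites
  xi <- as.numeric(s[i, c("x", "y", "z")])
  xj <- as.numeric(s[j, c("x", "y", "z")])
  dx <- xj - xi
  d <- sqrt(as.numeric(t(dx) %*% G %*% dx))
  if (d < 1e-12) stop("coincident sites: distance is zero, gradient undefined")
  cellSu <- structure@cell@su
  if (is.null(covariance) && all(is.na(cellSu)))
    return(list(value = d, su = NA_real_))
  gd <- as.numeric(G %*% dx) / d          # d(d)/d(xj); d(d)/d(xi) = -gd
  gradFrac <- c(-gd, gd)
  gradCell <- vapply(1:6, function(p) {
    Gp <- .metricTensorGrad(structure@cell, p)
    as.numeric(t(dx) %*% Gp %*% dx) / (2 * d)
  }, numeric(1))
  list(value = d, su = .suFromGradients(gradFrac, covariance, gradCell, cellSu))
}

#' Interatomic angle from fractional coordinates
#'
#' Angle at vertex site `j` between the bond vectors to sites `i` and `k`,
#' from the metric-tensor inner product. With a covariance matrix over the
#' nine fractional coordinates (ordered i, j, k) the standard uncertainty is
#' propagated to first order; cell-parameter su values contribute
#' independently.
#'
#' @param structure a [CrystalStructure-class].
#' @param i,j,k site indices; `j` is the vertex.
#' @param covariance optional 9x9 matrix over (xi..zi, xj..zj, xk..zk).
#' @return list with `value` (degrees) and `su` (degrees or `NA`).
#' @export
siteAngle <- function(structure, i, j, k, covariance = NULL) {
  G <- metricTensor(structure@cell)
  s <- structure@sites
  xi <- as.numeric(s[i, c("x", "y", "z")])
  xj <- as.numeric(s[j, c("x", "y", "z")])
  xk <- as.numeric(s[k, c("x", "y", "z")])
  u <- xi - xj; v <- xk - xj
  Gu <- as.numeric(G %*% u); Gv <- as.numeric(G %*% v)
  nu <- sqrt(sum(u * Gu)); nv <- sqrt(sum(v * Gv))
  if (nu < 1e-12 || nv < 1e-12)
    stop("undefined angle: a bond vector at the vertex has zero length")
  costh <- sum(u * Gv) / (nu * nv)
  costh <- max(-1, min(1, costh))
  theta <- acos(costh) * 180 / pi
  cellSu <- structure@cell@su
  if (is.null(covariance) && all(is.na(cellSu)))
    return(list(value = theta, su = NA_real_))
  sinth <- sqrt(max(1 - costh^2, 1e-24))
  r2d <- 180 / pi
  # dc/du and dc/dv in fractional space
  dcdu <- Gv / (nu * nv) - costh * Gu / nu^2
  dcdv <- Gu / (nu * nv) - costh * Gv / nv^2
  dthdu <- -dcdu / sinth * r2d
  dthdv <- -dcdv / sinth * r2d
  gradFrac <- c(dthdu, -(dthdu + dthdv), dthdv)   # d/d(xi), d/d(xj), d/d(xk)
  gradCell <- vapply(1:6, function(p) {
    Gp <- .metricTensorGrad(structure@cell, p)
    dc <- sum(u * (Gp %*% v)) / (nu * nv) -
      costh / 2 * (sum(u * (Gp %*% u)) / nu^2 + sum(v * (Gp %*% v)) / nv^2)
    -dc / sinth * r2d
  }, numeric(1))
  list(value = theta,
       su = .suFromGradients(gradFrac, covariance, gradCell, cellSu))
}

#' Tabulate distances and angles for a structure
#'
#' Convenience wrapper computing several distances and/or angles at once.
#'
#' @param structure a [CrystalStructure-class].
#' @param pairs two-column matrix of site-index pairs (distances), or NULL.
#' @param triples three-column matrix of site-index triples
#'   (i, vertex, k; angles), or NULL.
#' @param covariance optional covariance matrix over ALL site fractional
#'   coordinates of the structure, ordered site-by-site (x, y, z); the
#'   relevant 6x6/9x9 submatrix is extracted per geometry element.
#' @return data.frame with columns `kind`, `sites`, `value`, `su`.
#' @export
geometryTable <- function(structure, pairs = NULL, triples = NULL,
                          covariance = NULL) {
  out <- list()
  subCov <- function(sites) {
    if (is.null(covariance)) return(NULL)
    sel <- as.vector(vapply(sites, function(s) (s - 1L) * 3L + 1:3,
                            integer(3)))
    covariance[sel, sel, drop = FALSE]
  }
  if (!is.null(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    for (r in seq_len(nrow(pairs))) {
      d <- siteDistance(structure, pairs[r, 1], pairs[r, 2],
                        covariance = subCov(pairs[r, ]))
      out[[length(out) + 1L]] <- data.frame(
        kind = "distance", sites = paste(pairs[r, ], collapse = "-"),
        value = d$value, su = d$su, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(triples)) {
    triples <- matrix(as.integer(triples), ncol = 3)
    for (r in seq_len(nrow(triples))) {
      a <- siteAngle(structure, triples[r, 1], triples[r, 2], triples[r, 3],
                     covariance = subCov(triples[r, ]))
      out[[length(out) + 1L]] <- data.frame(
        kind = "angle", sites = paste(triples[r, ], collapse = "-"),
        value = a$value, su = a$su, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(kind = character(0), sites = character(0),
                      value = numeric(0), su = numeric(0)))
  do.call(rbind, out)
}
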