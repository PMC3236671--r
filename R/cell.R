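## Unit-cell arithmetic. The metric tensor G collects the inner products of
## the (generally oblique) cell basis vectors; squared distances between
## fractional-coordinate points are dx' G dx, so all geometry can stay in
## fractional coordinates. The orthogonalization matrix provides the
## independent Cartesian route used by the test oracles.

#' Construct a unit cell
#'
#' @param a,b,c cell lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @param su optional numeric(6) of standard uncertainties in the order
#'   (a, b, c, alpha, beta, gamma); `NA` where unknown.
#' @return a [UnitCell-class].
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                     su = rep(NA_real_, 6)) {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma), su = as.numeric(su))
}

#' Metric tensor of a unit cell
#'
#' @param cell a [UnitCell-class].
#' @return 3x3 symmetric positive-definite matrix (Angstrom^2).
#' @export
metricTensor <- function(cell) {
  .metricTensorRaw(cell@a, cell@b, cell@c, cell@alpha, cell@beta, cell@gamma)
}

#' Orthogonalization matrix (fractional to Cartesian)
#'
#' Standard crystallographic convention: the a axis along Cartesian x, b in
#' the x-y plane.
#'
#' @param cell a [UnitCell-class].
#' @return 3x3 matrix M with `cart = M %*% frac`.
#' @export
orthogonalizationMatrix <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell@alpha * d2r); cb <- cos(cell@beta * d2r)
  cg <- cos(cell@gamma * d2r); sg <- sin(cell@gamma * d2r)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(cell@a, cell@b * cg, cell@c * cb,
           0,      cell@b * sg, cell@c * (ca - cb * cg) / sg,
           0,      0,           cell@c * v / sg),
         3, 3, byrow = TRUE)
}

#' Cell volume in Angstrom^3
#' @param cell a [UnitCell-class].
#' @return numeric scalar.
#' @export
cellVolume <- function(cell) sqrt(det(metricTensor(cell)))

## partial derivative of G with respect to parameter k (1..6: a,b,c,al,be,ga;
## angle derivatives are per DEGREE)
.metricTensorGrad <- function(cell, k) {
  d2r <- pi / 180
  a <- cell@a; b <- cell@b; cc <- cell@c
  al <- cell@alpha * d2r; be <- cell@beta * d2r; ga <- cell@gamma * d2r
  ca <- cos(al); cb <- cos(be); cg <- cos(ga)
  switch(k,
    matrix(c(2 * a,  b * cg, cc * cb,
             b * cg, 0,      0,
             cc * cb, 0,     0), 3, 3),
    matrix(c(0,      a * cg, 0,
             a * cg, 2 * b,  cc * ca,
             0,      cc * ca, 0), 3, 3),
    matrix(c(0, 0, a * cb,
             0, 0, b * ca,
             a * cb, b * ca, 2 * cc), 3, 3),
    d2r * matrix(c(0, 0, 0,
                   0, 0, -b * cc * sin(al),
                   0, -b * cc * sin(al), 0), 3, 3),
    d2r * matrix(c(0, 0, -a * cc * sin(be),
                   0, 0, 0,
                   -a * cc * sin(be), 0, 0), 3, 3),
    d2r * matrix(c(0, -a * b * sin(ga), 0,
                   -a * b * sin(ga), 0, 0,
                   0, 0, 0), 3, 3))
}

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%g b=%g c=%g  alpha=%g beta=%g gamma=%g  V=%.3f A^3\n",
              object@a, object@b, object@c, object@alpha, object@beta,
              object@gamma, cellVolume(object)))
})
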