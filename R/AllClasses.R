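#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core CIF object model
##
## A CIF file maps onto three nested containers: a CifDocument holds ordered,
## case-insensitively unique data blocks; a CifBlock holds scalar items, loops
## (tables) and nested save frames; a CifLoop stores its values by column.
## All values are kept as raw strings -- numeric interpretation is on demand
## and never destructive, so "0.0250(10)" survives a round trip untouched.
## ---------------------------------------------------------------------------

#' CifLoop: a CIF table stored by column
#'
#' A loop is an ordered set of data names sharing one row count. Values are
#' stored column-wise as character vectors of raw CIF value strings. The loop
#' name is inferred from the member names (see [inferLoopName()]).
#'
#' @slot names character vector of data names (each starting with `_`),
#'   original spelling preserved.
#' @slot columns named list of character vectors, one per data name, all of
#'   equal length (the row count).
#' @slot name the inferred loop name.
#' @export
setClass("CifLoop",
  representation(names = "character", columns = "list", name = "character"),
  prototype(names = character(0), columns = list(), name = NA_character_))

setValidity("CifLoop", function(object) {
  msgs <- character(0)
  nm <- object@names
  if (length(nm) == 0L) msgs <- c(msgs, "a loop must have at least one data name")
  if (!all(startsWith(nm, "_"))) msgs <- c(msgs, "every loop data name must start with '_'")
  if (!identical(names(object@columns), nm))
    msgs <- c(msgs, "column names must equal the loop's data names, in order")
  lens <- vapply(object@columns, length, integer(1))
  if (length(lens) && length(unique(lens)) > 1L)
    msgs <- c(msgs, "all loop columns must have the same length")
  if (!all(vapply(object@columns, is.character, logical(1))))
    msgs <- c(msgs, "loop columns must be character vectors of raw value strings")
  if (anyDuplicated(tolower(nm)))
    msgs <- c(msgs, "loop data names must be unique (case-insensitive)")
  if (length(msgs)) msgs else TRUE
})

#' CifBlock: one CIF data block
#'
#' Holds scalar items, loops and (for dictionaries) nested save frames. A
#' given data name may appear at most once per block, across scalar items and
#' all loop columns, compared case-insensitively. `globals` holds items
#' inherited from a preceding `global_` frame when a file was parsed with
#' `permitGlobalBlocks = TRUE`; they are consulted by lookup but never
#' serialized as part of the block.
#'
#' @slot name block code, original spelling.
#' @slot items named list of scalar raw-string values.
#' @slot loops named list of [CifLoop-class] objects, keyed by inferred loop name.
#' @slot frames named list of nested `CifBlock` save frames.
#' @slot globals named list of raw-string items inherited from `global_` scope.
#' @export
setClass("CifBlock",
  representation(name = "character", items = "list", loops = "list",
                 frames = "list", globals = "list"),
  prototype(name = "", items = list(), loops = list(), frames = list(),
            globals = list()))

setValidity("CifBlock", function(object) {
  msgs <- character(0)
  if (length(object@name) != 1L) msgs <- c(msgs, "block name must be a single string")
  itemNames <- names(object@items)
  if (length(object@items) && (is.null(itemNames) || any(!nzchar(itemNames))))
    msgs <- c(msgs, "all items must be named")
  loopNames <- unlist(lapply(object@loops, function(l) l@names), use.names = FALSE)
  all_names <- c(itemNames, loopNames)
  if (anyDuplicated(tolower(all_names)))
    msgs <- c(msgs, "a data name may appear only once per block (items + loop columns)")
  if (!all(vapply(object@loops, is, logical(1), "CifLoop")))
    msgs <- c(msgs, "loops must be CifLoop objects")
  if (!all(vapply(object@frames, is, logical(1), "CifBlock")))
    msgs <- c(msgs, "save frames must be CifBlock objects")
  if (length(msgs)) msgs else TRUE
})

#' CifDocument: the in-memory form of one CIF file
#'
#' An ordered mapping of data-block code to [CifBlock-class]. Block codes are
#' unique under case-insensitive comparison; iteration order is insertion
#' order. Parsing diagnostics (see [cifDiagnostics()]) travel with the
#' document.
#'
#' @slot blocks named list of [CifBlock-class] objects.
#' @slot diagnostics data.frame of parse diagnostics (possibly empty).
#' @export
setClass("CifDocument",
  representation(blocks = "list", diagnostics = "data.frame"),
  prototype(blocks = list(), diagnostics = NULL))

setValidity("CifDocument", function(object) {
  msgs <- character(0)
  if (length(object@blocks)) {
    if (is.null(names(object@blocks)))
      msgs <- c(msgs, "blocks must be named by block code")
    if (anyDuplicated(tolower(names(object@blocks))))
      msgs <- c(msgs, "block codes must be unique (case-insensitive)")
    if (!all(vapply(object@blocks, is, logical(1), "CifBlock")))
      msgs <- c(msgs, "blocks must be CifBlock objects")
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Dictionaries and validation
## ---------------------------------------------------------------------------

#' CifDictionary: a parsed DDL1 or DDL2 data dictionary
#'
#' Maps canonical (lower-case) data names to definition records. A definition
#' is a plain list with elements `name`, `aliases`, `dataType` ("numb",
#' "char" or "any", or a DDL2 type code), `typeRegex` (optional pattern from
#' the dictionary's own type construct list), `enumeration`, `range`
#' (numeric length-2, `NA` for an open end), `listContext` ("must_loop",
#' "must_not_loop" or "either"), `linkedParent`, `suAllowed`, `mandatory`.
#'
#' @slot ddlVersion "ddl1" or "ddl2".
#' @slot definitions named list of definition records, keyed by canonical name.
#' @slot title dictionary title string.
#' @slot version dictionary version string.
#' @export
setClass("CifDictionary",
  representation(ddlVersion = "character", definitions = "list",
                 title = "character", version = "character"),
  prototype(ddlVersion = "ddl1", definitions = list(), title = NA_character_,
            version = NA_character_))

setValidity("CifDictionary", function(object) {
  msgs <- character(0)
  if (!object@ddlVersion %in% c("ddl1", "ddl2"))
    msgs <- c(msgs, "ddlVersion must be 'ddl1' or 'ddl2'")
  if (length(object@definitions) == 0L)
    msgs <- c(msgs, "a dictionary must contain at least one definition")
  if (length(msgs)) msgs else TRUE
})

#' CifValidationReport: findings from validating a document
#'
#' @slot findings data.frame with columns `block`, `name`, `code`,
#'   `severity`, `message`, `value`.
#' @slot nErrors number of error-severity findings.
#' @slot nWarnings number of warning-severity findings.
#' @export
setClass("CifValidationReport",
  representation(findings = "data.frame", nErrors = "integer",
                 nWarnings = "integer"))

setValidity("CifValidationReport", function(object) {
  f <- object@findings
  ok_err <- object@nErrors == sum(f$severity == "error")
  ok_warn <- object@nWarnings == sum(f$severity == "warning")
  if (ok_err && ok_warn) TRUE else "finding counts must equal tallies over findings"
})

## ---------------------------------------------------------------------------
## Crystallographic objects
## ---------------------------------------------------------------------------

#' UnitCell: cell lengths, angles and optional standard uncertainties
#'
#' Lengths in Angstrom, angles in degrees. `su` holds the six standard
#' uncertainties in the same order (a, b, c, alpha, beta, gamma), `NA` where
#' unknown.
#'
#' @slot a,b,c cell lengths (Angstrom), > 0.
#' @slot alpha,beta,gamma cell angles (degrees), in (0, 180).
#' @slot su numeric(6) standard uncertainties, NA allowed.
#' @export
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 su = "numeric"),
  prototype(alpha = 90, beta = 90, gamma = 90, su = rep(NA_real_, 6)))

setValidity("UnitCell", function(object) {
  msgs <- character(0)
  len <- c(object@a, object@b, object@c)
  ang <- c(object@alpha, object@beta, object@gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    msgs <- c(msgs, "cell lengths must be finite and > 0")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    msgs <- c(msgs, "cell angles must lie strictly between 0 and 180 degrees")
  if (length(object@su) != 6L) msgs <- c(msgs, "su must have length 6")
  if (!length(msgs)) {
    G <- .metricTensorRaw(len[1], len[2], len[3], ang[1], ang[2], ang[3])
    if (any(eigen(G, symmetric = TRUE, only.values = TRUE)$values <= 0))
      msgs <- c(msgs, "metric tensor is not positive definite")
  }
  if (length(msgs)) msgs else TRUE
})

#' SymOp: one space-group symmetry operation
#'
#' Rotation part is a 3x3 integer matrix with determinant +-1; translation
#' components are rationals with denominator in {1, 2, 3, 4, 6}, reduced
#' modulo 1. The canonical xyz triplet (e.g. `"-x,y+1/2,-z+1/2"`) is
#' recomputed on demand by [symOpXyz()] and round-trips through
#' [parseSymOp()].
#'
#' @slot rotation 3x3 numeric matrix with integer entries, det +-1.
#' @slot translation numeric(3) in `[0, 1)`.
#' @export
setClass("SymOp",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("SymOp", function(object) {
  msgs <- character(0)
  R <- object@rotation
  t <- object@translation
  if (!identical(dim(R), c(3L, 3L))) msgs <- c(msgs, "rotation must be 3x3")
  else {
    if (max(abs(R - round(R))) > 1e-9) msgs <- c(msgs, "rotation entries must be integers")
    else if (abs(abs(det(R)) - 1) > 1e-9) msgs <- c(msgs, "det(rotation) must be +1 or -1")
  }
  if (length(t) != 3L) msgs <- c(msgs, "translation must have length 3")
  else {
    if (any(t < -1e-9) || any(t >= 1))
      msgs <- c(msgs, "translation components must be reduced mod 1")
    t12 <- t * 12
    if (max(abs(t12 - round(t12))) > 1e-6)
      msgs <- c(msgs, "translations must be multiples of 1/12")
    else {
      den <- vapply(round(t12) %% 12, function(n) 12L %/% .gcd(n, 12L), integer(1))
      if (!all(den %in% c(1L, 2L, 3L, 4L, 6L)))
        msgs <- c(msgs, "translation denominators must be in {1,2,3,4,6}")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CrystalStructure: cell, symmetry and atomic sites
#'
#' Sites are held in a data.frame with columns `label`, `symbol`, `x`, `y`,
#' `z`, `occ`, `uiso`, their standard uncertainties (`suX`, ..., `suUiso`)
#' and optional anisotropic displacement components `u11`..`u23` with
#' `suU11`..`suU23` (all NA when the site is isotropic).
#'
#' @slot cell a [UnitCell-class].
#' @slot symops list of [SymOp-class] operations (identity-only for P1).
#' @slot spaceGroupSymbol Hermann-Mauguin symbol or `NA`.
#' @slot sites data.frame of atomic sites.
#' @export
setClass("CrystalStructure",
  representation(cell = "UnitCell", symops = "list",
                 spaceGroupSymbol = "character", sites = "data.frame"))

setValidity("CrystalStructure", function(object) {
  msgs <- character(0)
  if (!all(vapply(object@symops, is, logical(1), "SymOp")))
    msgs <- c(msgs, "symops must be SymOp objects")
  if (length(object@symops) == 0L) msgs <- c(msgs, "at least the identity operation is required")
  s <- object@sites
  need <- c("label", "symbol", "x", "y", "z", "occ", "uiso")
  if (!all(need %in% names(s)))
    msgs <- c(msgs, paste("sites must contain columns", paste(need, collapse = ", ")))
  else {
    if (nrow(s) && any(!is.finite(as.matrix(s[, c("x", "y", "z")]))))
      msgs <- c(msgs, "fractional coordinates must be finite")
    if (nrow(s) && any(s$occ < 0 | s$occ > 1.5, na.rm = TRUE))
      msgs <- c(msgs, "occupancies must lie in [0, 1.5]")
  }
  if (length(msgs)) msgs else TRUE
})

#' ReflectionSet: Miller indices with associated data columns
#'
#' One named data column per recognized family (e.g. `F_squared_meas`,
#' `F_calc`); sigmas are attached to their parent column by name. Missing
#' measurements ('?' in the CIF) are `NA`, never zero.
#'
#' @slot indices integer matrix, n x 3, columns h, k, l; no (0,0,0) row.
#' @slot data named list of numeric vectors aligned with `indices`.
#' @slot sigmas named list of numeric vectors; names are a subset of
#'   `names(data)`.
#' @slot cell a [UnitCell-class] or NULL.
#' @slot symops list of [SymOp-class], possibly empty.
#' @export
setClass("ReflectionSet",
  representation(indices = "matrix", data = "list", sigmas = "list",
                 cell = "ANY", symops = "list"),
  prototype(data = list(), sigmas = list(), cell = NULL, symops = list()))

setValidity("ReflectionSet", function(object) {
  msgs <- character(0)
  idx <- object@indices
  if (ncol(idx) != 3L) msgs <- c(msgs, "indices must have three columns (h, k, l)")
  else {
    if (nrow(idx) && any(rowSums(abs(idx)) == 0))
      msgs <- c(msgs, "indices must not contain the (0,0,0) reflection")
    n <- nrow(idx)
    if (!all(vapply(object@data, length, integer(1)) == n))
      msgs <- c(msgs, "all data columns must share the indices' length")
    if (!all(vapply(object@sigmas, length, integer(1)) == n))
      msgs <- c(msgs, "all sigma columns must share the indices' length")
    if (!all(names(object@sigmas) %in% names(object@data)))
      msgs <- c(msgs, "sigma columns must attach to an existing data column")
  }
  if (length(msgs)) msgs else TRUE
})

## small shared helpers needed by validity methods --------------------------

.gcd <- function(a, b) {
  a <- as.integer(abs(a)); b <- as.integer(abs(b))
  while (b != 0L) { tmp <- a %% b; a <- b; b <- tmp }
  if (a == 0L) 1L else a
}

.metricTensorRaw <- function(a, b, c, alpha, beta, gamma) {
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  matrix(c(a * a,      a * b * cg, a * c * cb,
           a * b * cg, b * b,      b * c * ca,
           a * c * cb, b * c * ca, c * c), 3, 3)
}
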