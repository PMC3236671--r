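## Space-group symmetry operations as (rotation | translation) pairs with
## xyz-triplet parsing/rendering, composition modulo lattice translations,
## and brute-force closure of generator sets. A small bundled table covers
## the groups used by the fixture generator: P1, P-1 and P2_1/c -- enough to
## exercise closure, composition and translation arithmetic without a full
## space-group table.

#' Construct a symmetry operation
#'
#' @param rotation 3x3 integer matrix, det +-1.
#' @param translation numeric(3); reduced modulo 1 on construction.
#' @return a [SymOp-class].
#' @export
symOp <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  t <- translation %% 1
  t[abs(t - 1) < 1e-9] <- 0
  new("SymOp", rotation = round(rotation), translation = round(t * 12) / 12)
}

#' Parse an xyz symmetry triplet
#'
#' Accepts triplets such as `"x,y,z"`, `"-x,y+1/2,-z+1/2"` or
#' `"1/2+x,-y,z"`. Fractions and decimals are both understood; whitespace
#' and case are ignored.
#'
#' @param xyz triplet string with three comma-separated coordinate
#'   expressions.
#' @return a [SymOp-class].
#' @export
parseSymOp <- function(xyz) {
  stopifnot(is.character(xyz), length(xyz) == 1L)
  s <- tolower(gsub("[ \t]", "", xyz))
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L || !all(nzchar(parts)))
    stop("unparseable xyz triplet: '", xyz, "'")
  if (!all(grepl("^[xyz0-9+*/.-]+$", parts)))
    stop("unparseable xyz triplet: '", xyz, "' (illegal characters)")
  evalAt <- function(expr, x, y, z) {
    v <- tryCatch(eval(parse(text = expr)[[1]],
                       envir = list(x = x, y = y, z = z),
                       enclos = baseenv()),
                  error = function(e) NA_real_)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("unparseable xyz triplet: '", xyz, "'")
    v
  }
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    t0 <- evalAt(parts[i], 0, 0, 0)
    R[i, 1] <- evalAt(parts[i], 1, 0, 0) - t0
    R[i, 2] <- evalAt(parts[i], 0, 1, 0) - t0
    R[i, 3] <- evalAt(parts[i], 0, 0, 1) - t0
    t[i] <- t0
  }
  if (max(abs(R - round(R))) > 1e-9)
    stop("unparseable xyz triplet: '", xyz, "' (non-integer rotation part)")
  symOp(R, t)
}

.fractionString <- function(t) {
  n <- as.integer(round(t * 12)) %% 12L
  if (n == 0L) return("")
  g <- .gcd(n, 12L)
  paste0(n %/% g, "/", 12L %/% g)
}

#' Render the canonical xyz triplet of a symmetry operation
#'
#' Letters come first with unit coefficients (e.g. `-x`), followed by the
#' translation as a reduced positive fraction, e.g. `"-x,y+1/2,-z+1/2"`.
#' `parseSymOp(symOpXyz(op))` reproduces `op` exactly.
#'
#' @param op a [SymOp-class].
#' @return character scalar.
#' @export
symOpXyz <- function(op) {
  letters3 <- c("x", "y", "z")
  rows <- vapply(1:3, function(i) {
    terms <- ""
    for (j in 1:3) {
      co <- round(op@rotation[i, j])
      if (co == 0) next
      sgn <- if (co > 0) "+" else "-"
      mag <- if (abs(co) == 1) "" else paste0(abs(co), "*")
      terms <- paste0(terms, sgn, mag, letters3[j])
    }
    fr <- .fractionString(op@translation[i])
    if (nzchar(fr)) terms <- paste0(terms, "+", fr)
    sub("^\\+", "", terms)
  }, character(1))
  paste(rows, collapse = ",")
}

#' Compose, compare and close sets of symmetry operations
#'
#' `symOpMultiply(a, b)` applies `b` first, then `a`; the translation is
#' reduced modulo 1 (composition modulo lattice translations).
#' `symOpEqual` compares rotation exactly and translation modulo 1.
#' `symOpClosure` grows a generator set to the full group by brute force.
#'
#' @param a,b [SymOp-class] objects.
#' @return `symOpMultiply`: a [SymOp-class]; `symOpEqual`: logical;
#'   `symOpClosure`: list of [SymOp-class].
#' @export
symOpMultiply <- function(a, b) {
  symOp(a@rotation %*% b@rotation,
        as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' @rdname symOpMultiply
#' @export
symOpEqual <- function(a, b) {
  if (max(abs(a@rotation - b@rotation)) > 1e-9) return(FALSE)
  dt <- (a@translation - b@translation) %% 1
  all(pmin(dt, 1 - dt) < 1e-9)
}

#' @rdname symOpMultiply
#' @param generators list of [SymOp-class] generator operations.
#' @param maxOrder safety cap on the group order.
#' @export
symOpClosure <- function(generators, maxOrder = 192L) {
  ops <- list(symOp())
  contains <- function(set, op) any(vapply(set, symOpEqual, logical(1), op))
  for (g in generators) if (!contains(ops, g)) ops <- c(ops, g)
  repeat {
    added <- FALSE
    for (a in ops) for (b in ops) {
      p <- symOpMultiply(a, b)
      if (!contains(ops, p)) {
        ops <- c(ops, p)
        added <- TRUE
        if (length(ops) > maxOrder)
          stop("generator set does not close within ", maxOrder, " operations")
      }
    }
    if (!added) break
  }
  ops
}

#' Is a set of symmetry operations closed under composition?
#'
#' @param symops list of [SymOp-class].
#' @return logical scalar.
#' @export
symOpsClosed <- function(symops) {
  contains <- function(op) any(vapply(symops, symOpEqual, logical(1), op))
  for (a in symops) for (b in symops)
    if (!contains(symOpMultiply(a, b))) return(FALSE)
  TRUE
}

## Bundled groups: generators and their Hermann-Mauguin spellings.
.SPACE_GROUPS <- list(
  "P1"     = list(generators = c("x,y,z"),
                  aliases = c("p1", "p 1")),
  "P-1"    = list(generators = c("-x,-y,-z"),
                  aliases = c("p-1", "p -1")),
  "P2_1/c" = list(generators = c("-x,y+1/2,-z+1/2", "-x,-y,-z"),
                  aliases = c("p2_1/c", "p21/c", "p 21/c", "p 1 21/c 1"))
)

#' The bundled space-group table
#'
#' Three groups (P1, P-1, P2_1/c) cover identity-only, centrosymmetric and
#' screw/glide translation arithmetic. `spaceGroupSymops` returns the full
#' general-position set (brute-force closure of the stored generators);
#' `spaceGroupNames` lists the available names.
#'
#' @param name group name or Hermann-Mauguin spelling (e.g. "P 21/c").
#' @return list of [SymOp-class] for `spaceGroupSymops`; character vector
#'   for `spaceGroupNames`.
#' @export
spaceGroupSymops <- function(name) {
  key <- .matchSpaceGroup(name)
  if (is.na(key)) stop("space group '", name, "' is not in the bundled table (",
                       paste(names(.SPACE_GROUPS), collapse = ", "), ")")
  gens <- lapply(.SPACE_GROUPS[[key]]$generators, parseSymOp)
  symOpClosure(gens)
}

#' @rdname spaceGroupSymops
#' @export
spaceGroupNames <- function() names(.SPACE_GROUPS)

.matchSpaceGroup <- function(name) {
  norm <- tolower(gsub("[ ()]", "", name))
  for (key in names(.SPACE_GROUPS)) {
    al <- gsub(" ", "", .SPACE_GROUPS[[key]]$aliases)
    if (norm %in% c(tolower(gsub("[ ]", "", key)), al)) return(key)
  }
  NA_character_
}

setMethod("show", "SymOp", function(object) {
  cat("SymOp:", symOpXyz(object), "\n")
})
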