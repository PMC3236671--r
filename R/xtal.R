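## Bridge between the CIF model and crystallographic objects. Reads and
## writes both the core-CIF (DDL1, underscore-separated) and mmCIF-pointed
## (DDL2) item names for the cell, symmetry, atom_site and refln categories.

.itemAny <- function(block, names, default = NULL) {
  for (nm in names) {
    v <- cifItem(block, nm, default = NULL)
    if (!is.null(v)) return(v)
  }
  default
}

.CELL_NAMES <- list(
  a = c("_cell_length_a", "_cell.length_a"),
  b = c("_cell_length_b", "_cell.length_b"),
  c = c("_cell_length_c", "_cell.length_c"),
  alpha = c("_cell_angle_alpha", "_cell.angle_alpha"),
  beta = c("_cell_angle_beta", "_cell.angle_beta"),
  gamma = c("_cell_angle_gamma", "_cell.angle_gamma"))

.SYMOP_XYZ_NAMES <- c("_symmetry_equiv_pos_as_xyz",
                      "_space_group_symop_operation_xyz",
                      "_symmetry_equiv.pos_as_xyz",
                      "_space_group_symop.operation_xyz")

.HM_NAMES <- c("_symmetry_space_group_name_H-M", "_space_group_name_H-M_alt",
               "_symmetry.space_group_name_H-M", "_space_group.name_H-M_alt")

#' Extract the crystal symmetry (cell + symmetry operations) from a block
#'
#' Cell values are parsed with their standard uncertainties. Symmetry comes
#' from the symop loop when present, otherwise from the Hermann-Mauguin
#' symbol via the bundled group table; absent both, identity-only symmetry
#' is returned with a warning.
#'
#' @param block a [CifBlock-class] carrying `_cell_length_*`/`_cell.length_*`
#'   items.
#' @return list with elements `cell` ([UnitCell-class]), `symops` (list of
#'   [SymOp-class]) and `spaceGroupSymbol` (string or `NA`).
#' @export
extractCrystalSymmetry <- function(block) {
  vals <- numeric(6); sus <- rep(NA_real_, 6)
  for (k in seq_along(.CELL_NAMES)) {
    raw <- .itemAny(block, .CELL_NAMES[[k]])
    if (is.null(raw))
      stop("missing cell item ", .CELL_NAMES[[k]][1], " in block '",
           block@name, "'")
    pc <- parseCifNumber(raw[1])
    if (pc$semantic != "number")
      stop("non-numeric cell item ", .CELL_NAMES[[k]][1], ": '", raw[1], "'")
    vals[k] <- pc$number; sus[k] <- pc$su
  }
  cell <- unitCell(vals[1], vals[2], vals[3], vals[4], vals[5], vals[6],
                   su = sus)
  symbol <- .itemAny(block, .HM_NAMES)
  symbol <- if (is.null(symbol)) NA_character_ else as.character(symbol[1])
  xyz <- .itemAny(block, .SYMOP_XYZ_NAMES)
  if (!is.null(xyz)) {
    symops <- lapply(as.character(xyz), parseSymOp)
  } else if (!is.na(symbol) && !is.na(.matchSpaceGroup(symbol))) {
    symops <- spaceGroupSymops(symbol)
  } else {
    warning("block '", block@name,
            "' carries no symmetry operations; assuming identity only (P1)")
    symops <- list(symOp())
  }
  list(cell = cell, symops = symops, spaceGroupSymbol = symbol)
}

#' Emit symmetry operations as a CIF loop
#'
#' The set must be closed under composition modulo lattice translations
#' (checked). The loop carries a 1-based id column and the canonical xyz
#' triplet column under the dialect-appropriate names; the identity is
#' always the first row.
#'
#' @param symops non-empty list of [SymOp-class].
#' @param dialect "ddl1" (`_symmetry_equiv_pos_*`) or "ddl2"
#'   (`_space_group_symop.*`).
#' @return a [CifLoop-class].
#' @export
symmetryOpsAsLoop <- function(symops, dialect = c("ddl1", "ddl2")) {
  dialect <- match.arg(dialect)
  stopifnot(length(symops) >= 1L)
  if (!symOpsClosed(symops))
    stop("group-closure error: the symmetry operations are not closed under composition")
  ident <- symOp()
  isId <- vapply(symops, symOpEqual, logical(1), ident)
  symops <- c(symops[isId], symops[!isId])
  xyz <- vapply(symops, symOpXyz, character(1))
  nms <- if (dialect == "ddl1")
    c("_symmetry_equiv_pos_site_id", "_symmetry_equiv_pos_as_xyz")
  else c("_space_group_symop.id", "_space_group_symop.operation_xyz")
  new("CifLoop",
      names = nms,
      columns = stats::setNames(list(as.character(seq_along(symops)), xyz), nms),
      name = inferLoopName(nms))
}

#' Construct a crystal structure
#'
#' @param cell a [UnitCell-class].
#' @param symops list of [SymOp-class]; defaults to identity only.
#' @param sites data.frame with at least `label`, `symbol`, `x`, `y`, `z`;
#'   missing numeric columns (`occ`, `uiso`, su and aniso columns) are
#'   filled with defaults/NA.
#' @param spaceGroupSymbol Hermann-Mauguin symbol or NA.
#' @return a [CrystalStructure-class].
#' @export
crystalStructure <- function(cell, symops = list(symOp()), sites,
                             spaceGroupSymbol = NA_character_) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  defaults <- list(occ = 1, uiso = NA_real_,
                   suX = NA_real_, suY = NA_real_, suZ = NA_real_,
                   suOcc = NA_real_, suUiso = NA_real_,
                   u11 = NA_real_, u22 = NA_real_, u33 = NA_real_,
                   u12 = NA_real_, u13 = NA_real_, u23 = NA_real_,
                   suU11 = NA_real_, suU22 = NA_real_, suU33 = NA_real_,
                   suU12 = NA_real_, suU13 = NA_real_, suU23 = NA_real_)
  for (nm in names(defaults))
    if (is.null(sites[[nm]])) sites[[nm]] <- rep(defaults[[nm]], nrow(sites))
  if (any(sites$occ > 1 + 1e-9, na.rm = TRUE))
    warning("site occupancy above 1 (disorder convention?)")
  new("CrystalStructure", cell = cell, symops = symops,
      spaceGroupSymbol = as.character(spaceGroupSymbol), sites = sites)
}

.ATOM_SITE <- list(
  label = c("_atom_site_label", "_atom_site.label"),
  symbol = c("_atom_site_type_symbol", "_atom_site.type_symbol"),
  x = c("_atom_site_fract_x", "_atom_site.fract_x"),
  y = c("_atom_site_fract_y", "_atom_site.fract_y"),
  z = c("_atom_site_fract_z", "_atom_site.fract_z"),
  occ = c("_atom_site_occupancy", "_atom_site.occupancy"),
  uiso = c("_atom_site_U_iso_or_equiv", "_atom_site.U_iso_or_equiv"))

.ANISO <- list(
  label = c("_atom_site_aniso_label", "_atom_site_anisotrop.id"),
  u11 = c("_atom_site_aniso_U_11", "_atom_site_anisotrop.U[1][1]"),
  u22 = c("_atom_site_aniso_U_22", "_atom_site_anisotrop.U[2][2]"),
  u33 = c("_atom_site_aniso_U_33", "_atom_site_anisotrop.U[3][3]"),
  u12 = c("_atom_site_aniso_U_12", "_atom_site_anisotrop.U[1][2]"),
  u13 = c("_atom_site_aniso_U_13", "_atom_site_anisotrop.U[1][3]"),
  u23 = c("_atom_site_aniso_U_23", "_atom_site_anisotrop.U[2][3]"))

#' Extract a full crystal structure (cell, symmetry, sites) from a block
#'
#' @param block a [CifBlock-class] with cell items and an `_atom_site` loop.
#' @return a [CrystalStructure-class].
#' @export
extractCrystalStructure <- function(block) {
  sym <- extractCrystalSymmetry(block)
  labels <- .itemAny(block, .ATOM_SITE$label)
  if (is.null(labels))
    stop("block '", block@name, "' has no _atom_site loop")
  n <- length(labels)
  sites <- data.frame(label = as.character(labels),
                      symbol = rep(NA_character_, n),
                      stringsAsFactors = FALSE)
  symb <- .itemAny(block, .ATOM_SITE$symbol)
  if (!is.null(symb)) sites$symbol <- as.character(symb)
  for (fld in c("x", "y", "z", "occ", "uiso")) {
    raw <- .itemAny(block, .ATOM_SITE[[fld]])
    if (is.null(raw)) {
      if (fld %in% c("x", "y", "z"))
        stop("missing fractional coordinate column in _atom_site loop")
      next
    }
    pc <- parseCifNumbers(raw)
    sites[[fld]] <- pc$value
    suName <- paste0("su", toupper(substr(fld, 1, 1)),
                     substring(fld, 2))
    sites[[suName]] <- pc$su
  }
  st <- crystalStructure(sym$cell, sym$symops, sites, sym$spaceGroupSymbol)
  alab <- .itemAny(block, .ANISO$label)
  if (!is.null(alab)) {
    idx <- match(as.character(alab), st@sites$label)
    for (fld in c("u11", "u22", "u33", "u12", "u13", "u23")) {
      raw <- .itemAny(block, .ANISO[[fld]])
      if (is.null(raw)) next
      pc <- parseCifNumbers(raw)
      st@sites[[fld]][idx] <- pc$value
      st@sites[[paste0("suU", substring(fld, 2))]][idx] <- pc$su
    }
  }
  st
}

#' Export a crystal structure to a CIF block
#'
#' Emits the cell items (with standard uncertainties re-attached in
#' parenthesis notation), the symmetry-operation loop, the `_atom_site`
#' loop, and an `_atom_site_aniso` loop when any site carries a 6-component
#' displacement tensor. `extractCrystalStructure()` of the emitted block
#' reproduces the numeric content.
#'
#' @param structure a [CrystalStructure-class].
#' @param blockName block code for the emitted block.
#' @param dialect "ddl1" (core CIF names) or "ddl2" (pointed names); site
#'   and cell items currently use core spellings for ddl1 and pointed
#'   spellings for ddl2.
#' @return a [CifBlock-class].
#' @export
structureAsCif <- function(structure, blockName = "structure",
                           dialect = c("ddl1", "ddl2")) {
  dialect <- match.arg(dialect)
  di <- if (dialect == "ddl1") 1L else 2L
  cell <- structure@cell
  blk <- cifBlock(blockName)
  cv <- c(cell@a, cell@b, cell@c, cell@alpha, cell@beta, cell@gamma)
  for (k in 1:6)
    blk <- setCifItem(blk, .CELL_NAMES[[k]][di],
                      formatNumberSu(cv[k], cell@su[k]))
  if (!is.na(structure@spaceGroupSymbol))
    blk <- setCifItem(blk, .HM_NAMES[di], structure@spaceGroupSymbol)
  symLoop <- symmetryOpsAsLoop(structure@symops, dialect)
  blk@loops[[symLoop@name]] <- symLoop
  s <- structure@sites
  fmt <- function(v, su) mapply(formatNumberSu, v, ifelse(is.na(su), NA, su))
  siteNames <- vapply(.ATOM_SITE, `[`, character(1), di)
  rows <- data.frame(
    label = s$label,
    symbol = ifelse(is.na(s$symbol), "?", s$symbol),
    x = fmt(s$x, s$suX), y = fmt(s$y, s$suY), z = fmt(s$z, s$suZ),
    occ = fmt(s$occ, s$suOcc),
    uiso = vapply(seq_len(nrow(s)), function(i)
      if (is.na(s$uiso[i])) "?" else formatNumberSu(s$uiso[i], s$suUiso[i]),
      character(1)),
    stringsAsFactors = FALSE)
  blk <- addLoop(blk, unname(siteNames), rows)
  hasAniso <- !is.na(s$u11)
  if (any(hasAniso)) {
    an <- s[hasAniso, , drop = FALSE]
    arows <- data.frame(
      label = an$label,
      u11 = fmt(an$u11, an$suU11), u22 = fmt(an$u22, an$suU22),
      u33 = fmt(an$u33, an$suU33), u12 = fmt(an$u12, an$suU12),
      u13 = fmt(an$u13, an$suU13), u23 = fmt(an$u23, an$suU23),
      stringsAsFactors = FALSE)
    blk <- addLoop(blk, vapply(.ANISO, `[`, character(1), di), arows)
  }
  blk
}

setMethod("show", "CrystalStructure", function(object) {
  cat(sprintf("CrystalStructure: %d site(s), %d symmetry operation(s)%s\n",
              nrow(object@sites), length(object@symops),
              if (!is.na(object@spaceGroupSymbol))
                paste0(", space group ", object@spaceGroupSymbol) else ""))
  show(object@cell)
})

## ---------------------------------------------------------------------------
## Reflection data
## ---------------------------------------------------------------------------

.REFLN_INDEX <- list(h = c("_refln_index_h", "_refln.index_h"),
                     k = c("_refln_index_k", "_refln.index_k"),
                     l = c("_refln_index_l", "_refln.index_l"))

## recognized data column families and the sigma column attached to each
.REFLN_FAMILIES <- list(
  F_squared_meas = list(data = c("_refln_F_squared_meas", "_refln.F_squared_meas"),
                        sigma = c("_refln_F_squared_sigma", "_refln.F_squared_sigma")),
  F_squared_calc = list(data = c("_refln_F_squared_calc", "_refln.F_squared_calc"),
                        sigma = character(0)),
  F_meas = list(data = c("_refln_F_meas", "_refln.F_meas_au"),
                sigma = c("_refln_F_sigma", "_refln.F_meas_sigma_au")),
  F_calc = list(data = c("_refln_F_calc", "_refln.F_calc_au"),
                sigma = character(0)))

#' Construct a reflection set
#'
#' @param indices integer matrix or data.frame with columns h, k, l.
#' @param data named list of numeric vectors (NA = missing measurement).
#' @param sigmas named list of numeric vectors; names must be a subset of
#'   `names(data)`.
#' @param cell optional [UnitCell-class].
#' @param symops optional list of [SymOp-class].
#' @return a [ReflectionSet-class].
#' @export
reflectionSet <- function(indices, data = list(), sigmas = list(),
                          cell = NULL, symops = list()) {
  m <- as.matrix(indices)
  storage.mode(m) <- "integer"
  colnames(m) <- c("h", "k", "l")
  new("ReflectionSet", indices = m, data = data, sigmas = sigmas,
      cell = cell, symops = symops)
}

#' Extract reflection data (Miller indices + data columns) from a block
#'
#' Recognizes the measured/calculated F and F-squared families under both
#' core and pointed names; sigmas attach to their parent columns. Rows whose
#' index triple does not parse as integers, and any (0,0,0) row, are dropped
#' with a warning. `?` values become `NA` (missing), never zero.
#'
#' @param block a [CifBlock-class] holding a `_refln` loop.
#' @return a [ReflectionSet-class]; with no recognized data family the set
#'   carries indices only and a warning is issued.
#' @export
extractReflections <- function(block) {
  h <- .itemAny(block, .REFLN_INDEX$h)
  k <- .itemAny(block, .REFLN_INDEX$k)
  l <- .itemAny(block, .REFLN_INDEX$l)
  if (is.null(h) || is.null(k) || is.null(l))
    stop("block '", block@name, "' has no _refln index columns")
  hn <- suppressWarnings(as.numeric(h))
  kn <- suppressWarnings(as.numeric(k))
  ln <- suppressWarnings(as.numeric(l))
  ok <- is.finite(hn) & is.finite(kn) & is.finite(ln) &
    hn == round(hn) & kn == round(kn) & ln == round(ln)
  if (any(!ok))
    warning(sum(!ok), " reflection row(s) with non-integer indices dropped")
  zero <- ok & hn == 0 & kn == 0 & ln == 0
  if (any(zero)) {
    warning(sum(zero), " (0,0,0) reflection row(s) dropped")
    ok <- ok & !zero
  }
  idx <- cbind(h = as.integer(hn[ok]), k = as.integer(kn[ok]),
               l = as.integer(ln[ok]))
  data <- list(); sigmas <- list()
  for (fam in names(.REFLN_FAMILIES)) {
    spec <- .REFLN_FAMILIES[[fam]]
    col <- .itemAny(block, spec$data)
    if (is.null(col)) next
    data[[fam]] <- parseCifNumbers(col)$value[ok]
    if (length(spec$sigma)) {
      sg <- .itemAny(block, spec$sigma)
      if (!is.null(sg)) sigmas[[fam]] <- parseCifNumbers(sg)$value[ok]
    }
  }
  if (length(data) == 0L)
    warning("no recognized reflection data columns in block '", block@name,
            "'; returning indices only")
  cell <- NULL; symops <- list()
  if (!is.null(.itemAny(block, .CELL_NAMES$a))) {
    sym <- suppressWarnings(extractCrystalSymmetry(block))
    cell <- sym$cell; symops <- sym$symops
  }
  reflectionSet(idx, data, sigmas, cell, symops)
}

#' Export a reflection set to a CIF block (fcf style)
#'
#' @param refl a [ReflectionSet-class].
#' @param blockName block code.
#' @param dialect "ddl1" or "ddl2" item spellings.
#' @return a [CifBlock-class]; `extractReflections()` of the result
#'   reproduces indices, data and sigmas.
#' @export
reflectionsAsCif <- function(refl, blockName = "reflections",
                             dialect = c("ddl1", "ddl2")) {
  dialect <- match.arg(dialect)
  di <- if (dialect == "ddl1") 1L else 2L
  blk <- cifBlock(blockName)
  if (!is.null(refl@cell)) {
    cv <- c(refl@cell@a, refl@cell@b, refl@cell@c,
            refl@cell@alpha, refl@cell@beta, refl@cell@gamma)
    for (kk in 1:6)
      blk <- setCifItem(blk, .CELL_NAMES[[kk]][di],
                        formatNumberSu(cv[kk], refl@cell@su[kk]))
  }
  if (length(refl@symops)) {
    symLoop <- symmetryOpsAsLoop(refl@symops, dialect)
    blk@loops[[symLoop@name]] <- symLoop
  }
  nms <- vapply(.REFLN_INDEX, `[`, character(1), di)
  cols <- list(as.character(refl@indices[, 1]),
               as.character(refl@indices[, 2]),
               as.character(refl@indices[, 3]))
  numToRaw <- function(v) ifelse(is.na(v), "?",
                                 vapply(v, formatNumberSu, character(1)))
  for (fam in names(refl@data)) {
    spec <- .REFLN_FAMILIES[[fam]]
    if (is.null(spec)) next
    nms <- c(nms, spec$data[di])
    cols <- c(cols, list(numToRaw(refl@data[[fam]])))
    if (!is.null(refl@sigmas[[fam]]) && length(spec$sigma)) {
      nms <- c(nms, spec$sigma[di])
      cols <- c(cols, list(numToRaw(refl@sigmas[[fam]])))
    }
  }
  names(cols) <- nms
  blk@loops[["_refln"]] <- new("CifLoop", names = unname(nms), columns = cols,
                               name = inferLoopName(unname(nms)))
  validObject(blk)
  blk
}

setMethod("show", "ReflectionSet", function(object) {
  cat(sprintf("ReflectionSet: %d reflection(s), data families: %s\n",
              nrow(object@indices),
              if (length(object@data)) paste(names(object@data), collapse = ", ")
              else "(none)"))
})
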