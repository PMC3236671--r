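## Accessors and editing operations for the CIF object model. All data-name
## lookups are case-insensitive (CIF convention); original spelling is
## preserved for output.

#' Number, names and subsetting of CIF documents and blocks
#'
#' `length()` counts blocks (document) or data names (block);
#' `names()` returns block codes / data names; `x[[name]]` retrieves a block
#' by code (case-insensitive) or an item/column by data name.
#'
#' @param x a [CifDocument-class] or [CifBlock-class].
#' @name cif-accessors
NULL

#' @rdname cif-accessors
#' @export
setMethod("length", "CifDocument", function(x) length(x@blocks))

#' @rdname cif-accessors
#' @export
setMethod("names", "CifDocument", function(x) names(x@blocks))

#' @rdname cif-accessors
#' @param i block code or data name (character, case-insensitive) or index.
#' @export
setMethod("[[", "CifDocument", function(x, i) {
  if (is.character(i)) {
    hit <- which(tolower(names(x@blocks)) == tolower(i))
    if (!length(hit)) stop("no data block named '", i, "'")
    x@blocks[[hit[1L]]]
  } else x@blocks[[i]]
})

#' @rdname cif-accessors
#' @export
setMethod("length", "CifBlock", function(x)
  length(x@items) + length(unlist(lapply(x@loops, function(l) l@names))))

#' @rdname cif-accessors
#' @export
setMethod("names", "CifBlock", function(x)
  c(names(x@items),
    unlist(lapply(x@loops, function(l) l@names), use.names = FALSE)))

#' @rdname cif-accessors
#' @export
setMethod("[[", "CifBlock", function(x, i) cifItem(x, i))

#' Look up a data item in a block
#'
#' Returns the scalar raw string for a non-looped item, or the full column
#' (character vector) for a looped item. Lookup is case-insensitive. Items
#' inherited from a `global_` scope are consulted after the block's own
#' names.
#'
#' @param block a [CifBlock-class].
#' @param name a data name (leading underscore).
#' @param default value returned when the name is absent; by default a
#'   missing-key error is raised naming the block and data name.
#' @return character scalar (item) or character vector (loop column).
#' @export
cifItem <- function(block, name, default) {
  stopifnot(is(block, "CifBlock"), is.character(name), length(name) == 1L)
  canon <- tolower(name)
  hit <- which(tolower(names(block@items)) == canon)
  if (length(hit)) return(block@items[[hit[1L]]])
  for (lp in block@loops) {
    j <- which(tolower(lp@names) == canon)
    if (length(j)) return(lp@columns[[j[1L]]])
  }
  hit <- which(tolower(names(block@globals)) == canon)
  if (length(hit)) return(block@globals[[hit[1L]]])
  if (!missing(default)) return(default)
  stop("data name '", name, "' not found in block '", block@name, "'")
}

#' Test whether a block holds a data name (case-insensitive)
#' @inheritParams cifItem
#' @return logical scalar.
#' @export
hasCifItem <- function(block, name) {
  !is.null(cifItem(block, name, default = NULL))
}

#' Retrieve a loop from a block
#'
#' A loop can be fetched by its inferred loop name or by any member data
#' name.
#'
#' @param block a [CifBlock-class].
#' @param name inferred loop name or member data name.
#' @return a [CifLoop-class] or `NULL` when no loop matches.
#' @export
cifLoop <- function(block, name) {
  stopifnot(is(block, "CifBlock"))
  canon <- tolower(name)
  hit <- which(tolower(names(block@loops)) == canon |
               tolower(vapply(block@loops, function(l) l@name, character(1))) == canon)
  if (length(hit)) return(block@loops[[hit[1L]]])
  for (lp in block@loops)
    if (canon %in% tolower(lp@names)) return(lp)
  NULL
}

#' Infer the name of a loop from its member data names
#'
#' The loop name is the longest common prefix of all member names, trimmed
#' back to (and excluding) the last separator character: underscore for
#' DDL1-style names, point for DDL2-style (mmCIF) names. When the common
#' prefix never reaches a separator beyond the leading underscore, the first
#' name is returned whole. This follows the reserved-prefix convention for
#' loop categories.
#'
#' @param names character vector of data names, all starting with `_`.
#' @param dialect "ddl1" or "ddl2"; defaults to "ddl2" when any name
#'   contains a point, else "ddl1".
#' @return the loop name (character scalar).
#' @examples
#' inferLoopName(c("_atom_site_label", "_atom_site_fract_x"))   # "_atom_site"
#' inferLoopName(c("_atom_site.id", "_atom_site.type_symbol"))  # "_atom_site"
#' @export
inferLoopName <- function(names, dialect = NULL) {
  if (length(names) == 0L) stop("cannot infer a loop name from zero data names")
  stopifnot(all(startsWith(names, "_")))
  if (is.null(dialect))
    dialect <- if (any(grepl(".", names, fixed = TRUE))) "ddl2" else "ddl1"
  dialect <- match.arg(dialect, c("ddl1", "ddl2"))
  sep <- if (dialect == "ddl1") "_" else "."
  pfx <- names[1L]
  for (nm in names[-1L]) {
    k <- 0L
    kmax <- min(nchar(pfx), nchar(nm))
    while (k < kmax &&
           substr(pfx, k + 1L, k + 1L) == substr(nm, k + 1L, k + 1L))
      k <- k + 1L
    pfx <- substr(pfx, 1L, k)
  }
  # last separator at position >= 2 (the leading underscore never counts)
  chars <- strsplit(pfx, "")[[1L]]
  sepPos <- which(chars == sep)
  sepPos <- sepPos[sepPos >= 2L]
  if (!length(sepPos)) return(names[1L])
  substr(pfx, 1L, max(sepPos) - 1L)
}

#' Add a loop to a block
#'
#' Values are stored by column; the loop name is set by [inferLoopName()].
#' Ragged rows raise a loop-shape error (the writer-side mirror of the
#' wrong-value-count syntax error); a data name already present in the block
#' raises a uniqueness error.
#'
#' @param block a [CifBlock-class].
#' @param names character vector of data names.
#' @param rows list of row vectors (each of length `length(names)`), or a
#'   data.frame/matrix with `length(names)` columns. Values are coerced to
#'   character.
#' @return the modified [CifBlock-class].
#' @export
addLoop <- function(block, names, rows) {
  stopifnot(is(block, "CifBlock"), is.character(names), length(names) >= 1L)
  names <- as.character(unname(names))
  if (is.data.frame(rows) || is.matrix(rows))
    rows <- lapply(seq_len(nrow(rows)), function(i) unlist(rows[i, ], use.names = FALSE))
  lens <- vapply(rows, length, integer(1))
  if (any(lens != length(names)))
    stop("loop-shape error: every row must have ", length(names),
         " values (the value count must be an exact multiple of the tag count)")
  existing <- tolower(c(base::names(block@items),
                        unlist(lapply(block@loops, function(l) l@names))))
  clash <- names[tolower(names) %in% existing]
  if (length(clash))
    stop("data name(s) already present in block '", block@name, "': ",
         paste(clash, collapse = ", "))
  m <- if (length(rows)) do.call(rbind, lapply(rows, as.character))
       else matrix(character(0), 0, length(names))
  cols <- lapply(seq_along(names), function(j) unname(m[, j]))
  base::names(cols) <- names
  lname <- inferLoopName(names)
  key <- lname; sfx <- 2L
  while (key %in% base::names(block@loops)) {
    key <- paste0(lname, "_", sfx); sfx <- sfx + 1L
  }
  block@loops[[key]] <- new("CifLoop", names = names, columns = cols,
                            name = lname)
  validObject(block)
  block
}

#' Set a scalar item in a block
#'
#' Replaces any existing value under the same (case-insensitive) name,
#' including a loop column (the column is removed from its loop; removing
#' the last column removes the loop).
#'
#' @param block a [CifBlock-class].
#' @param name data name.
#' @param value raw value string (coerced to character).
#' @return the modified block.
#' @export
setCifItem <- function(block, name, value) {
  stopifnot(is(block, "CifBlock"), startsWith(name, "_"))
  block <- removeCifItem(block, name, missingOk = TRUE)
  block@items[[name]] <- as.character(value)
  validObject(block)
  block
}

#' Remove a data item from a block
#'
#' Removing a looped name removes that column; removing the last column of a
#' loop removes the loop.
#'
#' @param block a [CifBlock-class].
#' @param name data name (case-insensitive).
#' @param missingOk logical; when `FALSE` (default), removing an absent name
#'   is an error.
#' @return the modified block.
#' @export
removeCifItem <- function(block, name, missingOk = FALSE) {
  canon <- tolower(name)
  hit <- which(tolower(names(block@items)) == canon)
  if (length(hit)) { block@items <- block@items[-hit[1L]]; return(block) }
  for (key in names(block@loops)) {
    lp <- block@loops[[key]]
    j <- which(tolower(lp@names) == canon)
    if (length(j)) {
      if (length(lp@names) == 1L) block@loops[[key]] <- NULL
      else block@loops[[key]] <- new("CifLoop", names = lp@names[-j],
                                     columns = lp@columns[-j], name = lp@name)
      return(block)
    }
  }
  if (!missingOk) stop("data name '", name, "' not found in block '",
                       block@name, "'")
  block
}

#' Iterate over the rows of a loop
#'
#' @param loop a [CifLoop-class].
#' @return a list of named character vectors, one per row, preserving column
#'   order; an empty list for a zero-row loop.
#' @export
loopRows <- function(loop) {
  stopifnot(is(loop, "CifLoop"))
  nr <- if (length(loop@columns)) length(loop@columns[[1L]]) else 0L
  lapply(seq_len(nr), function(i)
    vapply(loop@columns, `[[`, character(1), i))
}

#' Row count of a loop
#' @param loop a [CifLoop-class].
#' @return integer.
#' @export
loopNrow <- function(loop) {
  if (length(loop@columns)) length(loop@columns[[1L]]) else 0L
}

#' Construct a document or block programmatically
#'
#' @param blocks named list of [CifBlock-class] objects (names are block codes).
#' @return a [CifDocument-class].
#' @export
cifDocument <- function(blocks = list()) {
  if (length(blocks) && is.null(names(blocks)))
    names(blocks) <- vapply(blocks, function(b) b@name, character(1))
  new("CifDocument", blocks = blocks, diagnostics = .emptyDiagnostics())
}

#' @rdname cifDocument
#' @param name block code.
#' @param items named list (or named character vector) of scalar raw values.
#' @export
cifBlock <- function(name = "", items = list()) {
  new("CifBlock", name = name, items = as.list(items))
}

#' Structural equality of documents, blocks and loops
#'
#' Compares block codes, item names/values (raw strings, original spelling)
#' and loop contents, recursively through save frames. Diagnostics and
#' `global_` scopes are ignored.
#'
#' @param a,b objects of the same model class.
#' @return logical scalar.
#' @export
cifIdentical <- function(a, b) {
  if (is(a, "CifDocument") && is(b, "CifDocument")) {
    if (!identical(names(a@blocks), names(b@blocks))) return(FALSE)
    return(all(mapply(cifIdentical, a@blocks, b@blocks)))
  }
  if (is(a, "CifBlock") && is(b, "CifBlock")) {
    if (!identical(a@name, b@name)) return(FALSE)
    if (!identical(names(a@items), names(b@items))) return(FALSE)
    if (!identical(lapply(a@items, as.character), lapply(b@items, as.character)))
      return(FALSE)
    if (length(a@loops) != length(b@loops)) return(FALSE)
    if (!all(mapply(cifIdentical, a@loops, b@loops))) return(FALSE)
    if (!identical(names(a@frames), names(b@frames))) return(FALSE)
    return(all(mapply(cifIdentical, a@frames, b@frames)) || length(a@frames) == 0L)
  }
  if (is(a, "CifLoop") && is(b, "CifLoop")) {
    return(identical(a@names, b@names) &&
           identical(lapply(a@columns, unname), lapply(b@columns, unname)))
  }
  FALSE
}

## show() methods print the serialized CIF, the natural human-readable form.

setMethod("show", "CifDocument", function(object) {
  d <- cifDiagnostics(object)
  cat(sprintf("CifDocument with %d block(s)%s\n", length(object@blocks),
              if (nrow(d)) sprintf(" [%d diagnostic(s)]", nrow(d)) else ""))
  cat(writeCif(object))
})

setMethod("show", "CifBlock", function(object) {
  cat(.serializeBlock(object, cifWriteOptions()), sep = "")
})

setMethod("show", "CifLoop", function(object) {
  cat(.serializeLoop(object, cifWriteOptions()), sep = "")
})
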