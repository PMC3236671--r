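## CIF serialization. Output is ASCII, LF line endings, and always re-parses
## strictly to a model equal to the input under raw-value comparison.
## Quoting is decided per value; a per-loop row template (sprintf format)
## skips the per-value quoting checks entirely, which is the fast path for
## large reflection loops.

#' Formatting controls for CIF output
#'
#' @param indentLoopValues spaces of indentation for looped data names and
#'   values (default 2).
#' @param dataNameFieldWidth minimum width of the data-name column for
#'   scalar items; 0 means a single separating space.
#' @param alignColumns logical; pad loop columns to a common width.
#' @param loopRowTemplates named list mapping a loop name to an `sprintf`
#'   format applied verbatim to each row (`%s`/`%d`/`%f`-style). The
#'   template bypasses per-value quoting checks by design.
#' @return a list of class `CifWriteOptions`.
#' @export
cifWriteOptions <- function(indentLoopValues = 2L, dataNameFieldWidth = 0L,
                            alignColumns = FALSE, loopRowTemplates = list()) {
  stopifnot(indentLoopValues >= 0L, dataNameFieldWidth >= 0L)
  structure(list(indentLoopValues = as.integer(indentLoopValues),
                 dataNameFieldWidth = as.integer(dataNameFieldWidth),
                 alignColumns = isTRUE(alignColumns),
                 loopRowTemplates = loopRowTemplates),
            class = "CifWriteOptions")
}

.RESERVED_VALUE_RE <- "^(data_|save_|loop_|global_|stop_)"

## Can `raw` be closed by the given quote char? Only if the char followed by
## whitespace (or at the end) never occurs inside.
.quotable <- function(raw, q) {
  !grepl(paste0(q, "([ \t]|$)"), raw)
}

#' Render one value with the quoting its content requires
#'
#' Plain tokens pass through unchanged; values containing whitespace, a
#' leading quote, `[`, `]`, `_`, `#`, `$`, `;`, or matching a reserved word
#' (`data_...`, `loop_`, `save_...`, `global_`, `stop_`) are quoted; a value
#' containing a newline, or both quote styles unquotably, becomes a
#' semicolon text field. The single quote is preferred; the empty string
#' renders as `''`. `?` and `.` pass through (they are the CIF
#' unknown/inapplicable markers and are stored as raw values).
#'
#' @param raw the raw value string.
#' @return the rendered value text; multi-line for text fields.
#' @export
quoteValue <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  if (grepl("[^\\x20-\\x7e\\t\\n]", raw, perl = TRUE))
    stop("serialization error: value contains non-ASCII or control characters: ",
         substr(gsub("[^\\x20-\\x7e]", "?", raw, perl = TRUE), 1, 40))
  needsField <- grepl("\n", raw, fixed = TRUE) ||
    (!.quotable(raw, "'") && !.quotable(raw, '"'))
  if (needsField) {
    if (grepl("(^|\n);", raw))
      stop("quoting error: value contains a line starting with ';' and cannot be written as a text field")
    if (grepl("\n$", raw) || grepl("^\n", raw))
      stop("quoting error: leading/trailing newline in a value is not preserved by a text field")
    return(paste0(";\n", raw, "\n;"))
  }
  if (raw == "") return("''")
  plainOk <- !grepl("[ \t]", raw) &&
    !substr(raw, 1, 1) %in% c("'", "\"", "_", "#", "$", "[", "]", ";") &&
    !grepl(.RESERVED_VALUE_RE, raw, ignore.case = TRUE)
  if (plainOk) return(raw)
  if (.quotable(raw, "'")) return(paste0("'", raw, "'"))
  paste0('"', raw, '"')
}

.templateConverters <- function(fmt) {
  specs <- regmatches(fmt, gregexpr("%[-+ #0-9.]*[a-zA-Z]", fmt))[[1]]
  vapply(specs, function(s) {
    conv <- substr(s, nchar(s), nchar(s))
    if (conv %in% c("d", "i")) "integer"
    else if (conv %in% c("f", "e", "g", "E", "G")) "double"
    else "character"
  }, character(1))
}

.serializeLoop <- function(loop, options) {
  ind <- strrep(" ", options$indentLoopValues)
  out <- c("loop_\n", paste0(ind, loop@names, "\n"))
  nr <- loopNrow(loop)
  if (nr == 0L) return(out)
  tmpl <- options$loopRowTemplates[[loop@name]]
  if (!is.null(tmpl)) {
    # fast path: no per-value quoting checks, the template is applied verbatim
    conv <- .templateConverters(tmpl)
    cols <- loop@columns
    if (length(conv) == length(cols)) {
      cols <- mapply(function(col, cl) switch(cl,
               integer = as.integer(col), double = as.numeric(col), col),
               cols, conv, SIMPLIFY = FALSE)
    }
    rows <- do.call(sprintf, c(list(tmpl), unname(cols)))
    return(c(out, paste0(rows, "\n")))
  }
  rendered <- lapply(loop@columns, function(col)
    vapply(col, quoteValue, character(1), USE.NAMES = FALSE))
  multiline <- vapply(rendered, function(col) any(grepl("\n", col)), logical(1))
  if (options$alignColumns && !any(multiline)) {
    rendered <- lapply(rendered, function(col)
      formatC(col, width = max(nchar(col)), flag = "-"))
  }
  rows <- do.call(paste, c(rendered, sep = " "))
  if (any(unlist(lapply(rendered, grepl, pattern = "\n", fixed = TRUE)))) {
    # rows containing text fields need the field at line starts: emit value
    # by value instead
    rows <- vapply(seq_len(nr), function(i) {
      vals <- vapply(rendered, `[[`, character(1), i)
      parts <- character(0)
      cur <- ""
      for (v in vals) {
        if (grepl("\n", v, fixed = TRUE)) {
          if (nzchar(cur)) parts <- c(parts, cur)
          parts <- c(parts, v)
          cur <- ""
        } else cur <- if (nzchar(cur)) paste(cur, v) else v
      }
      if (nzchar(cur)) parts <- c(parts, cur)
      paste(parts, collapse = "\n")
    }, character(1))
    return(c(out, paste0(rows, "\n")))
  }
  c(out, paste0(ind, rows, "\n"))
}

.serializeItems <- function(items, options) {
  if (!length(items)) return(character(0))
  width <- max(options$dataNameFieldWidth, 0L)
  unlist(lapply(names(items), function(nm) {
    v <- quoteValue(as.character(items[[nm]]))
    tag <- formatC(nm, width = width, flag = "-")
    if (grepl("\n", v, fixed = TRUE)) paste0(nm, "\n", v, "\n")
    else if (nchar(tag) + 1L + nchar(v) > 2048L) paste0(nm, "\n", v, "\n")
    else paste0(tag, " ", v, "\n")
  }))
}

.serializeBlock <- function(block, options, heading = TRUE) {
  out <- if (heading) paste0("data_", block@name, "\n") else character(0)
  out <- c(out, .serializeItems(block@items, options))
  for (lp in block@loops) out <- c(out, .serializeLoop(lp, options))
  for (fn in names(block@frames)) {
    out <- c(out, paste0("save_", fn, "\n"),
             .serializeItems(block@frames[[fn]]@items, options))
    for (lp in block@frames[[fn]]@loops)
      out <- c(out, .serializeLoop(lp, options))
    out <- c(out, "save_\n")
  }
  out
}

#' Serialize a document, block or loop to CIF text
#'
#' The output re-parses in strict mode to a model equal to the input under
#' raw-value comparison (modulo whitespace and comments). With `file` given,
#' the text is written with LF line endings and the path returned invisibly.
#'
#' @param x a [CifDocument-class], [CifBlock-class] or [CifLoop-class].
#' @param file optional output path.
#' @param options a [cifWriteOptions()] list.
#' @return the CIF text (character scalar), or the path invisibly when
#'   `file` is given.
#' @examples
#' b <- cifBlock("x", list("_a" = "1"))
#' cat(writeCif(cifDocument(list(x = b))))
#' @export
writeCif <- function(x, file = NULL, options = cifWriteOptions()) {
  pieces <-
    if (is(x, "CifDocument")) {
      unlist(lapply(x@blocks, .serializeBlock, options = options),
             use.names = FALSE)
    } else if (is(x, "CifBlock")) {
      .serializeBlock(x, options)
    } else if (is(x, "CifLoop")) {
      .serializeLoop(x, options)
    } else stop("writeCif() handles CifDocument, CifBlock or CifLoop objects")
  text <- paste(pieces, collapse = "")
  if (is.null(file)) return(text)
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeChar(text, con, eos = NULL)
  invisible(file)
}
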