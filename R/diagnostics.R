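## Diagnostics: every lexing/parsing/validation finding is one row of a plain
## data.frame. Error classes 1..12 follow the numbered taxonomy of common CIF
## syntax errors (missing quotes, junk preamble, semicolon mismatch, extra or
## missing values, missing/garbled headings, non-ASCII, leading '[', loop
## count, global_); class 0 is used for uncategorized findings.

.emptyDiagnostics <- function() {
  data.frame(line = integer(0), column = integer(0), offset = integer(0),
             severity = character(0), class = integer(0),
             message = character(0), recovered = logical(0),
             stringsAsFactors = FALSE)
}

.diag <- function(line, column, offset, severity, class, message, recovered) {
  data.frame(line = as.integer(line), column = as.integer(column),
             offset = as.integer(offset), severity = severity,
             class = as.integer(class), message = message,
             recovered = recovered, stringsAsFactors = FALSE)
}

#' Short descriptions of the twelve common CIF syntax error classes
#'
#' Returns the taxonomy used in diagnostics' `class` column. Class 0 marks
#' findings outside the numbered taxonomy (e.g. duplicate data names).
#'
#' @return named character vector, names "1".."12".
#' @export
cifErrorClasses <- function() {
  c("1"  = "missing quote for a string without whitespace",
    "2"  = "missing quote for a string containing whitespace",
    "3"  = "non-comment text prepended before the first data block",
    "4"  = "mismatching semicolon delimiters for a multi-line text field",
    "5"  = "more than one data value for a tag",
    "6"  = "missing data value for a tag",
    "7"  = "data items before any data-block heading",
    "8"  = "data-block heading containing whitespace or illegal characters",
    "9"  = "non-ASCII characters",
    "10" = "unquoted string with '[' as the first character",
    "11" = "wrong number of values for a loop",
    "12" = "inclusion of an unnamed global_ block")
}

#' Retrieve the diagnostics attached to a parsed document
#'
#' @param x a [CifDocument-class] returned by [parseCif()] or [readCif()].
#' @return data.frame with columns `line`, `column`, `offset`, `severity`
#'   ("error"/"warning"), `class` (0..12), `message`, `recovered`.
#' @export
cifDiagnostics <- function(x) {
  stopifnot(is(x, "CifDocument"))
  x@diagnostics
}

## Raise a classified syntax error carrying the offending diagnostic row.
.stopSyntax <- function(d) {
  row <- d[1L, , drop = FALSE]
  msg <- sprintf("CIF syntax error [class %d] at line %d, column %d: %s",
                 row$class, row$line, row$column, row$message)
  cond <- structure(class = c("cifSyntaxError", "error", "condition"),
                    list(message = msg, call = sys.call(-1), diagnostic = row))
  stop(cond)
}
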