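## Line-oriented CIF 1.1 lexer.
##
## CIF lexing is inherently line-sensitive: quoted strings may not cross an
## end-of-line, and a semicolon in column 1 opens or closes a multi-line text
## field. The lexer therefore walks the input line by line, maintaining only
## the text-field state across lines. Every token records its raw span and
## 1-based line/column plus a 0-based character offset, so diagnostics can
## point at the exact source position.

#' Parsing options for the CIF lexer/parser
#'
#' @param strict logical; in strict mode the first error-severity diagnostic
#'   aborts with a classified condition. In lenient mode parsing continues
#'   after documented recovery actions, every one recorded as a diagnostic
#'   with `recovered = TRUE`.
#' @param permitGlobalBlocks logical; lenient mode only. When `TRUE`,
#'   `global_` frames (forbidden by CIF 1.1 but used e.g. by the CCP4
#'   monomer library) are accepted and their items become a fallback lookup
#'   scope for every subsequent data block.
#' @param maxLineLengthWarn integer or `NA`; lines longer than this emit a
#'   warning-severity diagnostic (CIF 1.1 nominally caps lines at 2048
#'   characters; real files exceed it, so this is never an error).
#' @param keepComments logical; emit COMMENT tokens instead of discarding.
#' @return a list of class `CifParseOptions`.
#' @export
cifParseOptions <- function(strict = FALSE, permitGlobalBlocks = FALSE,
                            maxLineLengthWarn = 2048L, keepComments = FALSE) {
  structure(list(strict = isTRUE(strict),
                 permitGlobalBlocks = isTRUE(permitGlobalBlocks),
                 maxLineLengthWarn = maxLineLengthWarn,
                 keepComments = isTRUE(keepComments)),
            class = "CifParseOptions")
}

.NONASCII_RE <- "[^\\x20-\\x7e\\t\\n\\r]"   # legal characters: ASCII 9, 10, 13, 32..126

.tokenKindOfBare <- function(tok) {
  lt <- tolower(tok)
  if (startsWith(lt, "data_")) return("DATA_HEADING")
  if (lt == "loop_") return("LOOP")
  if (lt == "global_") return("GLOBAL")
  if (lt == "stop_") return("STOP")
  if (lt == "save_") return("SAVE_END")
  if (startsWith(lt, "save_")) return("SAVE_HEADING")
  if (startsWith(tok, "_")) return("TAG")
  "VALUE_UNQUOTED"
}

## Internal workhorse: never aborts; returns list(tokens=df, diagnostics=df).
.tokenizeImpl <- function(text, options) {
  stopifnot(is.character(text), length(text) == 1L)
  kinds <- character(0); texts <- character(0); vals <- character(0)
  lns <- integer(0); cols <- integer(0); offs <- integer(0)
  diags <- list()

  emit <- function(kind, raw, value, line, col, off) {
    kinds[[length(kinds) + 1L]] <<- kind
    texts[[length(texts) + 1L]] <<- raw
    vals[[length(vals) + 1L]] <<- value
    lns[[length(lns) + 1L]] <<- line
    cols[[length(cols) + 1L]] <<- col
    offs[[length(offs) + 1L]] <<- off
  }
  addDiag <- function(line, col, off, severity, class, message,
                      recovered = !options$strict) {
    diags[[length(diags) + 1L]] <<- .diag(line, col, off, severity, class,
                                          message, recovered && severity == "error")
  }

  if (nchar(text) == 0L) {
    emit("EOF", "", "", 1L, 1L, 0L)
    return(list(tokens = .tokensDf(kinds, texts, vals, lns, cols, offs),
                diagnostics = .bindDiags(diags)))
  }

  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (substring(text, nchar(text)) == "\n") lines <- c(lines, "")
  rawLens <- nchar(lines)
  lineStart <- c(0L, cumsum(rawLens + 1L))   # 0-based offset of each line start

  checkAscii <- function(tok, line, col, off) {
    if (grepl(.NONASCII_RE, tok, perl = TRUE, useBytes = FALSE))
      addDiag(line, col, off, "error", 9L,
              sprintf("non-ASCII or control character in token starting '%s'",
                      substr(gsub(.NONASCII_RE, "?", tok, perl = TRUE), 1, 20)))
  }

  scanLine <- function(s, lineno, colBase = 0L) {
    pos <- 1L
    n <- nchar(s)
    while (pos <= n) {
      rest <- substring(s, pos)
      ws <- regmatches(rest, regexpr("^[ \t\r]+", rest))
      if (length(ws)) { pos <- pos + nchar(ws); next }
      if (pos > n) break
      off <- lineStart[lineno] + colBase + pos - 1L
      col <- colBase + pos
      ch <- substring(s, pos, pos)
      if (ch == "#") {
        raw <- substring(s, pos)
        if (options$keepComments) emit("COMMENT", raw, raw, lineno, col, off)
        break
      }
      if (ch == "'" || ch == '"') {
        body <- substring(s, pos + 1L)
        # closing quote = same quote char followed by whitespace or EOL
        pat <- paste0(ch, "(?=[ \t\r]|$)")
        m <- regexpr(pat, body, perl = TRUE)
        if (m > 0L) {
          inner <- substr(body, 1L, m - 1L)
          raw <- substr(s, pos, pos + m)
          kind <- if (ch == "'") "VALUE_SQUOTED" else "VALUE_DQUOTED"
          checkAscii(inner, lineno, col, off)
          emit(kind, raw, inner, lineno, col, off)
          pos <- pos + m + 1L
        } else {
          inner <- body
          cls <- if (grepl("[ \t]", inner)) 2L else 1L
          addDiag(lineno, col, off, "error", cls,
                  sprintf("missing closing %s quote; string closed at end of line",
                          if (ch == "'") "single" else "double"))
          checkAscii(inner, lineno, col, off)
          kind <- if (ch == "'") "VALUE_SQUOTED" else "VALUE_DQUOTED"
          emit(kind, substring(s, pos), inner, lineno, col, off)
          pos <- n + 1L
        }
        next
      }
      m <- regexpr("[ \t\r]", rest)
      end <- if (m > 0L) m - 1L else nchar(rest)
      tok <- substr(rest, 1L, end)
      checkAscii(tok, lineno, col, off)
      emit(.tokenKindOfBare(tok), tok, tok, lineno, col, off)
      pos <- pos + end
    }
  }

  i <- 1L
  nlin <- length(lines)
  while (i <= nlin) {
    line <- sub("\r$", "", lines[i])
    if (!is.na(options$maxLineLengthWarn) &&
        nchar(line) > options$maxLineLengthWarn)
      addDiag(i, 1L, lineStart[i], "warning", 0L,
              sprintf("line exceeds %d characters", options$maxLineLengthWarn),
              recovered = FALSE)
    if (startsWith(line, ";")) {
      firstRest <- substring(line, 2L)
      j <- i + 1L
      body <- character(0)
      closed <- FALSE
      while (j <= nlin) {
        lj <- sub("\r$", "", lines[j])
        if (startsWith(lj, ";")) { closed <- TRUE; break }
        body <- c(body, lj)
        j <- j + 1L
      }
      if (!closed) {
        addDiag(i, 1L, lineStart[i], "error", 4L,
                "semicolon text field opened here is never closed; consumed to end of input",
                recovered = FALSE)
        i <- nlin + 1L
        next
      }
      parts <- c(if (nzchar(firstRest)) firstRest, body)
      value <- paste(parts, collapse = "\n")
      raw <- paste(c(line, body, ";"), collapse = "\n")
      checkAscii(value, i, 1L, lineStart[i])
      emit("VALUE_TEXTFIELD", raw, value, i, 1L, lineStart[i])
      closing <- sub("\r$", "", lines[j])
      scanLine(substring(closing, 2L), j, colBase = 1L)
      i <- j + 1L
      next
    }
    scanLine(line, i)
    i <- i + 1L
  }
  emit("EOF", "", "", nlin, rawLens[nlin] + 1L, nchar(text))
  list(tokens = .tokensDf(kinds, texts, vals, lns, cols, offs),
       diagnostics = .bindDiags(diags))
}

.tokensDf <- function(kinds, texts, vals, lns, cols, offs) {
  data.frame(kind = kinds, text = texts, value = vals,
             line = lns, column = cols, offset = offs,
             stringsAsFactors = FALSE)
}

.bindDiags <- function(diags) {
  if (length(diags) == 0L) return(.emptyDiagnostics())
  do.call(rbind, diags)
}

#' Tokenize CIF text
#'
#' Splits CIF 1.1 text into a token stream. Quoted strings never span an
#' end-of-line; an unterminated semicolon text field consumes the rest of the
#' input and emits an unrecoverable class-4 diagnostic; characters outside
#' ASCII 9, 10, 13, 32..126 yield class-9 diagnostics.
#'
#' @param text character scalar (the whole file; decode bytes as latin1 so
#'   offending bytes remain locatable).
#' @param options a [cifParseOptions()] list. In strict mode the first
#'   error-severity diagnostic aborts.
#' @return list with elements `tokens` (data.frame: `kind`, `text` = raw
#'   span, `value` = semantic content, `line`, `column`, `offset`) and
#'   `diagnostics` (see [cifDiagnostics()]).
#' @export
tokenizeCif <- function(text, options = cifParseOptions()) {
  res <- .tokenizeImpl(text, options)
  if (options$strict) {
    err <- res$diagnostics[res$diagnostics$severity == "error", , drop = FALSE]
    if (nrow(err)) .stopSyntax(err)
  }
  res
}
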