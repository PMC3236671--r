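## Token-stream parser building the CifDocument model.
##
## Two modes: strict raises a classified condition at the first
## error-severity diagnostic; lenient applies a documented recovery per
## error class and records it (recovered = TRUE):
##   1/2 missing quotes        -> string closed at end of line (lexer)
##   3   junk preamble         -> skipped up to the first data_ heading
##   4   unterminated ; field  -> rest of input consumed; partial document
##   5   extra value for a tag -> first value kept, extras discarded
##   6   tag without value     -> tag dropped
##   7   items before heading  -> synthetic block with empty name
##   8   garbled heading       -> heading accepted verbatim
##   9/10 illegal characters   -> offending tag-value pair discarded
##   11  loop value count      -> entire loop rejected (loop-scoped finding)
##   12  global_ frame         -> merged lookup scope if permitted, else
##                                items discarded

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a grammar violation into the common-error taxonomy
#'
#' Total function mapping a diagnostic context to the lowest-numbered
#' matching class of the twelve common CIF syntax errors (see
#' [cifErrorClasses()]), or 0 when none matches.
#'
#' @param context list with optional elements `state` (a parser-state label
#'   such as "unterminated_quote", "preamble_junk", "extra_value",
#'   "tag_without_value", "items_before_heading", "heading_illegal",
#'   "loop_count", "value_position"), `text` (the offending token text) and
#'   `recoveredValue` (for quote recovery).
#' @return integer in 0..12.
#' @export
classifyCifError <- function(context) {
  tok <- context$text %||% ""
  state <- context$state %||% ""
  if (state == "unterminated_quote")
    return(if (grepl("[ \t]", context$recoveredValue %||% tok)) 2L else 1L)
  if (state == "preamble_junk") return(3L)
  if (state == "unterminated_textfield") return(4L)
  if (state == "extra_value") return(5L)
  if (state == "tag_without_value") return(6L)
  if (state == "items_before_heading") return(7L)
  if (state == "heading_illegal") return(8L)
  if (grepl(.NONASCII_RE, tok, perl = TRUE)) return(9L)
  if (state %in% c("value_position", "loop_value") && startsWith(tok, "[")) return(10L)
  if (state == "loop_count") return(11L)
  if (tolower(tok) == "global_") return(12L)
  0L
}

.VALUE_KINDS <- c("VALUE_UNQUOTED", "VALUE_SQUOTED", "VALUE_DQUOTED",
                  "VALUE_TEXTFIELD")

#' Parse CIF text into a document
#'
#' @param text character scalar holding the whole CIF file.
#' @param options a [cifParseOptions()] list.
#' @return a [CifDocument-class]; diagnostics are available through
#'   [cifDiagnostics()]. In strict mode a returned document implies zero
#'   error-severity diagnostics; lenient mode records every recovery.
#' @examples
#' doc <- parseCif("data_x\n_a 1\n")
#' cifItem(doc[["x"]], "_a")
#' @export
parseCif <- function(text, options = cifParseOptions()) {
  lex <- .tokenizeImpl(text, options)
  toks <- lex$tokens
  diags <- list(lex$diagnostics)

  kind <- toks$kind; txt <- toks$text; val <- toks$value
  ln <- toks$line; cl <- toks$column; off <- toks$offset
  n <- nrow(toks)

  blocks <- list()
  pendingGlobals <- list()

  curBlock <- NULL    # builder list(name, items, loops, frames, globals)
  curFrame <- NULL
  curGlobal <- NULL   # builder for a permitted global_ frame
  globalDiscard <- FALSE

  addDiag <- function(i, severity, class, message, recovered = !options$strict,
                      line = NULL, column = NULL, offset = NULL) {
    diags[[length(diags) + 1L]] <<- .diag(
      line %||% ln[i], column %||% cl[i], offset %||% off[i],
      severity, class, message, recovered && severity == "error")
  }

  newBuilder <- function(name) list(name = name, items = list(),
                                    loops = list(), frames = list(),
                                    globals = pendingGlobals)

  allNamesOf <- function(b) {
    c(names(b$items),
      unlist(lapply(b$loops, function(l) l@names), use.names = FALSE))
  }

  removeName <- function(b, canon) {
    hit <- tolower(names(b$items)) == canon
    if (any(hit)) b$items <- b$items[!hit]
    for (lname in names(b$loops)) {
      lp <- b$loops[[lname]]
      keep <- tolower(lp@names) != canon
      if (!all(keep)) {
        if (!any(keep)) b$loops[[lname]] <- NULL
        else b$loops[[lname]] <- new("CifLoop", names = lp@names[keep],
                                     columns = lp@columns[keep],
                                     name = lp@name)
      }
    }
    b
  }

  setItemIn <- function(b, name, value, i) {
    canon <- tolower(name)
    if (canon %in% tolower(allNamesOf(b))) {
      addDiag(i, "error", 0L,
              sprintf("duplicate data name %s in block '%s'; last value wins",
                      name, b$name))
      b <- removeName(b, canon)
    }
    b$items[[name]] <- value
    b
  }

  finishFrame <- function(i) {
    if (is.null(curFrame)) return(invisible())
    fb <- .builderToBlock(curFrame)
    curBlock$frames[[curFrame$name]] <<- fb
    curFrame <<- NULL
  }

  finishGlobal <- function() {
    if (is.null(curGlobal)) return(invisible())
    pendingGlobals <<- utils::modifyList(pendingGlobals, curGlobal$items)
    curGlobal <<- NULL
    globalDiscard <<- FALSE
  }

  finishBlock <- function(i) {
    finishFrame(i)
    finishGlobal()
    if (is.null(curBlock)) return(invisible())
    nm <- curBlock$name
    hit <- which(tolower(names(blocks)) == tolower(nm))
    blk <- .builderToBlock(curBlock)
    if (length(hit)) {
      addDiag(i, "error", 0L,
              sprintf("duplicate data block '%s'; last definition wins", nm))
      blocks[[hit[1L]]] <<- blk
      names(blocks)[hit[1L]] <<- nm
    } else {
      blocks[[length(blocks) + 1L]] <<- blk
      names(blocks)[length(blocks)] <<- nm
    }
    curBlock <<- NULL
  }

  target <- function() {
    if (!is.null(curFrame)) "frame"
    else if (!is.null(curGlobal)) "global"
    else "block"
  }
  getT <- function() switch(target(), frame = curFrame, global = curGlobal,
                            block = curBlock)
  setT <- function(b) switch(target(),
                             frame = curFrame <<- b,
                             global = curGlobal <<- b,
                             block = curBlock <<- b)

  openBlock <- function(i) {
    finishBlock(i)
    nm <- sub("^data_", "", txt[i], ignore.case = TRUE)
    if (!nzchar(nm))
      addDiag(i, "error", classifyCifError(list(state = "heading_illegal")),
              "empty data-block heading")
    # stray bare values right after a heading: an intended heading that
    # contained whitespace; re-attach verbatim (class 8).
    j <- i + 1L
    while (j <= n && kind[j] %in% c("VALUE_UNQUOTED", "VALUE_SQUOTED",
                                    "VALUE_DQUOTED")) {
      addDiag(j, "error", classifyCifError(list(state = "heading_illegal")),
              sprintf("data-block heading continued by '%s'; accepted verbatim",
                      txt[j]))
      nm <- paste(nm, val[j])
      j <- j + 1L
    }
    curBlock <<- newBuilder(nm)
    j
  }

  dropPair <- function(tagName, i, cls) {
    addDiag(i, "error", cls,
            sprintf("illegal characters in value for %s; tag-value pair discarded",
                    tagName))
  }

  p <- 1L
  sawPreambleJunk <- FALSE
  while (p <= n) {
    k <- kind[p]
    if (k == "COMMENT") { p <- p + 1L; next }
    if (k == "EOF") break

    if (is.null(curBlock) && is.null(curGlobal)) {
      if (k == "DATA_HEADING") { p <- openBlock(p); next }
      if (k == "GLOBAL") {
        # handled below by shared branch
      } else if (k %in% c("TAG", "LOOP")) {
        addDiag(p, "error",
                classifyCifError(list(state = "items_before_heading")),
                "data items before any data-block heading; placed in a block with an empty name")
        curBlock <- newBuilder("")
        next
      } else {
        if (!sawPreambleJunk) {
          addDiag(p, "error", classifyCifError(list(state = "preamble_junk",
                                                    text = txt[p])),
                  "non-comment text before the first data block; skipped")
          sawPreambleJunk <- TRUE
        }
        p <- p + 1L
        next
      }
    }

    if (k == "DATA_HEADING") { p <- openBlock(p); next }

    if (k == "GLOBAL") {
      finishBlock(p)
      if (options$strict || !options$permitGlobalBlocks) {
        addDiag(p, "error", classifyCifError(list(text = txt[p])),
                "global_ frame is forbidden by CIF 1.1; its items are discarded")
        curGlobal <- newBuilder("global")
        globalDiscard <- TRUE
      } else {
        addDiag(p, "warning", classifyCifError(list(text = txt[p])),
                "global_ frame accepted (non-strict mode); items become fallback scope",
                recovered = FALSE)
        curGlobal <- newBuilder("global")
        globalDiscard <- FALSE
      }
      p <- p + 1L
      next
    }

    if (k == "SAVE_HEADING") {
      if (target() == "global") {
        addDiag(p, "error", 0L, "save frame inside global_ frame; skipped")
        p <- p + 1L
        next
      }
      if (!is.null(curFrame)) {
        addDiag(p, "error", 0L, "nested save frame; previous frame closed")
        finishFrame(p)
      }
      curFrame <- list(name = sub("^save_", "", txt[p], ignore.case = TRUE),
                       items = list(), loops = list(), frames = list(),
                       globals = list())
      p <- p + 1L
      next
    }

    if (k == "SAVE_END") {
      if (is.null(curFrame))
        addDiag(p, "warning", 0L, "save_ terminator outside a save frame; ignored",
                recovered = FALSE)
      else finishFrame(p)
      p <- p + 1L
      next
    }

    if (k == "STOP") {
      addDiag(p, "warning", 0L, "stop_ is a STAR construct; ignored",
              recovered = FALSE)
      p <- p + 1L
      next
    }

    if (k == "TAG") {
      tagName <- txt[p]
      if (p + 1L <= n && kind[p + 1L] %in% .VALUE_KINDS) {
        vi <- p + 1L
        bad9 <- grepl(.NONASCII_RE, val[vi], perl = TRUE) ||
                grepl(.NONASCII_RE, tagName, perl = TRUE)
        bad10 <- kind[vi] == "VALUE_UNQUOTED" && startsWith(val[vi], "[")
        if (bad10)
          dropPair(tagName, vi, classifyCifError(list(state = "value_position",
                                                      text = val[vi])))
        else if (bad9)
          dropPair(tagName, vi, 9L)   # lexer already located the bad character
        else if (!globalDiscard || target() != "global")
          setT(setItemIn(getT(), tagName, val[vi], vi))
        p <- vi + 1L
        # extra values for a single tag: keep the first, discard the rest
        if (p <= n && kind[p] %in% .VALUE_KINDS) {
          addDiag(p, "error", classifyCifError(list(state = "extra_value")),
                  sprintf("more than one data value for %s; extras discarded",
                          tagName))
          while (p <= n && kind[p] %in% .VALUE_KINDS) p <- p + 1L
        }
      } else {
        addDiag(p, "error", classifyCifError(list(state = "tag_without_value")),
                sprintf("missing data value for %s; tag dropped", tagName))
        p <- p + 1L
      }
      next
    }

    if (k == "LOOP") {
      loopLine <- ln[p]; loopCol <- cl[p]; loopOff <- off[p]
      q <- p + 1L
      tags <- character(0)
      while (q <= n && kind[q] == "TAG") { tags <- c(tags, txt[q]); q <- q + 1L }
      if (length(tags) == 0L) {
        addDiag(p, "error", 0L, "loop_ without data names; ignored")
        p <- q
        next
      }
      vals <- character(0); vkinds <- character(0)
      while (q <= n && kind[q] %in% c(.VALUE_KINDS, "COMMENT", "STOP")) {
        if (kind[q] == "STOP") {
          addDiag(q, "warning", 0L, "stop_ loop terminator ignored",
                  recovered = FALSE)
        } else if (kind[q] != "COMMENT") {
          vals <- c(vals, val[q]); vkinds <- c(vkinds, kind[q])
        }
        q <- q + 1L
      }
      ntags <- length(tags)
      lname <- inferLoopName(tags)
      if (length(vals) %% ntags != 0L) {
        addDiag(NULL, "error", classifyCifError(list(state = "loop_count")),
                sprintf("wrong number of values (%d) for loop %s with %d data names; loop rejected",
                        length(vals), lname, ntags),
                line = loopLine, column = loopCol, offset = loopOff)
      } else {
        nrows <- length(vals) %/% ntags
        m <- if (nrows) matrix(vals, nrow = nrows, ncol = ntags, byrow = TRUE)
             else matrix(character(0), 0, ntags)
        km <- if (nrows) matrix(vkinds, nrow = nrows, ncol = ntags, byrow = TRUE)
              else matrix(character(0), 0, ntags)
        badRow <- rep(FALSE, nrows)
        if (nrows) for (ri in seq_len(nrows)) {
          b10 <- km[ri, ] == "VALUE_UNQUOTED" & startsWith(m[ri, ], "[")
          b9 <- grepl(.NONASCII_RE, m[ri, ], perl = TRUE)
          if (any(b10))
            addDiag(NULL, "error", 10L,
                    sprintf("unquoted value '%s' starts with '['; loop row %d discarded",
                            m[ri, which(b10)[1]], ri),
                    line = loopLine, column = loopCol, offset = loopOff)
          if (any(b9) && !any(b10))
            addDiag(NULL, "error", 9L,
                    sprintf("non-ASCII value in loop %s; row %d discarded", lname, ri),
                    line = loopLine, column = loopCol, offset = loopOff)
          badRow[ri] <- any(b10) || any(b9)
        }
        m <- m[!badRow, , drop = FALSE]
        cols <- lapply(seq_len(ntags), function(j) unname(m[, j]))
        names(cols) <- tags
        b <- getT()
        for (tg in tags) {
          canon <- tolower(tg)
          if (canon %in% tolower(allNamesOf(b))) {
            addDiag(NULL, "error", 0L,
                    sprintf("duplicate data name %s in block '%s'; last value wins",
                            tg, b$name),
                    line = loopLine, column = loopCol, offset = loopOff)
            b <- removeName(b, canon)
          }
        }
        key <- lname
        sfx <- 2L
        while (key %in% names(b$loops)) { key <- paste0(lname, "_", sfx); sfx <- sfx + 1L }
        b$loops[[key]] <- new("CifLoop", names = tags, columns = cols, name = lname)
        if (!globalDiscard || target() != "global") setT(b)
      }
      p <- q
      next
    }

    if (k %in% .VALUE_KINDS) {
      addDiag(p, "error", classifyCifError(list(state = "extra_value")),
              sprintf("data value '%s' without a preceding tag; discarded",
                      substr(txt[p], 1, 30)))
      while (p <= n && kind[p] %in% .VALUE_KINDS) p <- p + 1L
      next
    }

    p <- p + 1L  # unreachable safety
  }
  finishBlock(n)

  allDiags <- .bindDiags(diags)
  if (nrow(allDiags)) allDiags <- allDiags[order(allDiags$offset), , drop = FALSE]
  rownames(allDiags) <- NULL
  if (options$strict) {
    err <- allDiags[allDiags$severity == "error", , drop = FALSE]
    if (nrow(err)) .stopSyntax(err)
  }
  new("CifDocument", blocks = blocks, diagnostics = allDiags)
}

.builderToBlock <- function(b) {
  new("CifBlock", name = b$name, items = b$items, loops = b$loops,
      frames = b$frames, globals = b$globals)
}

#' Read and parse a CIF file
#'
#' Bytes are decoded as latin1 (one byte, one character) so that offending
#' non-ASCII bytes can be located and reported rather than corrupting the
#' stream.
#'
#' @param path path to a CIF 1.1 file.
#' @param options a [cifParseOptions()] list.
#' @return a [CifDocument-class].
#' @export
readCif <- function(path, options = cifParseOptions()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, what = "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "latin1"
  # strip a UTF-8 BOM if present
  if (length(raw) >= 3 && identical(raw[1:3], as.raw(c(0xef, 0xbb, 0xbf))))
    txt <- substring(txt, 4L)
  parseCif(txt, options)
}
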