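## Validation of a parsed document against a data dictionary. Every finding
## is routed through a replaceable handler before inclusion in the report,
## so an application can escalate, filter or log findings as it sees fit.
## Severity policy (a documented package choice): unknown data name is a
## warning; type, enumeration, range, su-where-forbidden, list-context and
## missing-parent violations are errors.

.finding <- function(block, name, code, severity, message, value = NA_character_) {
  data.frame(block = block, name = name, code = code, severity = severity,
             message = message, value = value, stringsAsFactors = FALSE)
}

#' The default validation handler: accumulate silently
#'
#' A handler is a `function(finding)` called once per finding (a one-row
#' data.frame with columns `block`, `name`, `code`, `severity`, `message`,
#' `value`). The handler decides continuation: signalling a condition aborts
#' the validation run. The default does nothing, so all findings accumulate
#' into the report.
#'
#' @return a handler function.
#' @export
cifDefaultHandler <- function() function(finding) invisible(NULL)

#' Validate a document against a data dictionary
#'
#' For every data item in every block: an unknown name yields a warning; a
#' `numb`-typed value that does not parse under the CIF numeric convention,
#' a value outside the definition's enumeration or range, a standard
#' uncertainty where the dictionary forbids one, an item looped where the
#' dictionary requires a scalar (or vice versa), and a child item present
#' without its linked parent all yield errors. `?` (unknown) and `.`
#' (inapplicable) values are always accepted.
#'
#' @param document a [CifDocument-class].
#' @param dictionary a [CifDictionary-class].
#' @param handler a `function(finding)`; see [cifDefaultHandler()]. Every
#'   finding is passed to the handler before inclusion in the report.
#' @return a [CifValidationReport-class].
#' @examples
#' dict <- loadDictionary(toyDdl1Dictionary())
#' doc <- parseCif("data_t\n_toy_count -1\n")
#' validateCif(doc, dict)
#' @export
validateCif <- function(document, dictionary, handler = cifDefaultHandler()) {
  stopifnot(is(document, "CifDocument"), is(dictionary, "CifDictionary"),
            is.function(handler))
  findings <- list()
  add <- function(f) {
    handler(f)
    findings[[length(findings) + 1L]] <<- f
  }

  checkValue <- function(blockName, name, raw, def) {
    pc <- parseCifNumber(raw)
    if (pc$semantic %in% c("unknown", "inapplicable")) return(invisible())
    if (def$dataType == "numb") {
      if (pc$semantic != "number") {
        add(.finding(blockName, name, "type", "error",
                     sprintf("value '%s' is not a number (type numb)", raw), raw))
        return(invisible())
      }
      if (!is.na(pc$su) && !def$suAllowed)
        add(.finding(blockName, name, "su_not_allowed", "error",
                     sprintf("value '%s' carries a standard uncertainty but the dictionary forbids one", raw),
                     raw))
      if (!is.null(def$range)) {
        lo <- def$range[1]; hi <- def$range[2]
        if ((!is.na(lo) && pc$number < lo) || (!is.na(hi) && pc$number > hi))
          add(.finding(blockName, name, "range", "error",
                       sprintf("value %s outside permitted range [%s, %s]", raw,
                               ifelse(is.na(lo), "-inf", lo),
                               ifelse(is.na(hi), "inf", hi)), raw))
      }
    } else if (!is.na(def$typeRegex)) {
      if (!grepl(paste0("^(", def$typeRegex, ")$"), raw))
        add(.finding(blockName, name, "type", "error",
                     sprintf("value '%s' does not match the dictionary pattern for type '%s'",
                             raw, def$dataType), raw))
    }
    if (!is.null(def$enumeration) && !(raw %in% def$enumeration))
      add(.finding(blockName, name, "enumeration", "error",
                   sprintf("value '%s' not in permitted set {%s}", raw,
                           paste(def$enumeration, collapse = ", ")), raw))
    invisible()
  }

  checkName <- function(blockName, name, values, looped, blk) {
    def <- dictDefinition(dictionary, name)
    if (is.null(def)) {
      add(.finding(blockName, name, "unknown_name", "warning",
                   sprintf("data name %s is not defined in dictionary '%s'",
                           name, dictionary@title)))
      return(invisible())
    }
    if (looped && def$listContext == "must_not_loop")
      add(.finding(blockName, name, "list_context", "error",
                   sprintf("%s must not appear in a loop", name)))
    if (!looped && def$listContext == "must_loop")
      add(.finding(blockName, name, "list_context", "error",
                   sprintf("%s must appear in a loop", name)))
    if (!is.na(def$linkedParent) && !hasCifItem(blk, def$linkedParent))
      add(.finding(blockName, name, "missing_parent", "error",
                   sprintf("%s is present but its parent item %s is absent",
                           name, def$linkedParent)))
    for (v in values) checkValue(blockName, name, v, def)
    invisible()
  }

  for (bi in seq_along(document@blocks)) {
    blk <- document@blocks[[bi]]
    blockName <- names(document@blocks)[bi]
    for (nm in names(blk@items))
      checkName(blockName, nm, blk@items[[nm]], looped = FALSE, blk = blk)
    for (lp in blk@loops)
      for (j in seq_along(lp@names))
        checkName(blockName, lp@names[j], lp@columns[[j]], looped = TRUE,
                  blk = blk)
  }

  f <- if (length(findings)) do.call(rbind, findings) else
    data.frame(block = character(0), name = character(0), code = character(0),
               severity = character(0), message = character(0),
               value = character(0), stringsAsFactors = FALSE)
  rownames(f) <- NULL
  new("CifValidationReport", findings = f,
      nErrors = sum(f$severity == "error"),
      nWarnings = sum(f$severity == "warning"))
}

setMethod("show", "CifValidationReport", function(object) {
  cat(sprintf("CifValidationReport: %d error(s), %d warning(s)\n",
              object@nErrors, object@nWarnings))
  if (nrow(object@findings)) {
    f <- object@findings
    for (i in seq_len(min(nrow(f), 20L)))
      cat(sprintf("  [%s] %s %s: %s\n", f$severity[i], f$block[i],
                  f$name[i], f$message[i]))
    if (nrow(f) > 20L) cat(sprintf("  ... and %d more\n", nrow(f) - 20L))
  }
})
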