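## Loading of CIF data dictionaries (DDL1 and DDL2).
##
## DDL1 dictionaries (core CIF style) define one data item per data block,
## with global_ frames carrying defaults; DDL2 dictionaries (mmCIF style)
## hold one save frame per item inside a single data block. Both are parsed
## with the lenient grammar and permitGlobalBlocks = TRUE.
##
## Implemented attribute subset -- DDL1: _name, _type, _type_conditions,
## _enumeration, _enumeration_range, _list, _list_reference. DDL2:
## _item.name, _item.mandatory_code, _item_type.code (with the dictionary's
## own _item_type_list.construct regexes when present), _item_enumeration.value,
## _item_range.minimum/.maximum, _item_linked.parent_name/child_name,
## _item_aliases.alias_name. Unrecognized attributes are ignored.

.defaultDefinition <- function(name) {
  list(name = name, aliases = character(0), dataType = "any",
       typeRegex = NA_character_, enumeration = NULL,
       range = NULL, listContext = "either", linkedParent = NA_character_,
       suAllowed = FALSE, mandatory = FALSE)
}

.parseDdl1Range <- function(txt) {
  # "min:max" with either end empty for open
  parts <- strsplit(txt, ":", fixed = TRUE)[[1]]
  lo <- if (length(parts) >= 1 && nzchar(parts[1])) as.numeric(parts[1]) else NA_real_
  hi <- if (length(parts) >= 2 && nzchar(parts[2])) as.numeric(parts[2]) else NA_real_
  c(lo, hi)
}

.ddl1Definition <- function(block) {
  nm <- cifItem(block, "_name", default = NULL)
  if (is.null(nm)) return(NULL)
  nm <- as.character(nm)          # may be a looped column of aliases
  def <- .defaultDefinition(nm[1])
  def$aliases <- nm[-1]
  ty <- cifItem(block, "_type", default = NULL)
  if (!is.null(ty)) def$dataType <- tolower(ty[1])
  tc <- cifItem(block, "_type_conditions", default = NULL)
  if (!is.null(tc)) def$suAllowed <- any(tolower(tc) %in% c("esd", "su"))
  en <- cifItem(block, "_enumeration", default = NULL)
  if (!is.null(en)) def$enumeration <- as.character(en)
  rg <- cifItem(block, "_enumeration_range", default = NULL)
  if (!is.null(rg)) def$range <- .parseDdl1Range(rg[1])
  li <- cifItem(block, "_list", default = NULL)
  if (!is.null(li))
    def$listContext <- switch(tolower(li[1]), yes = "must_loop",
                              no = "must_not_loop", "either")
  lr <- cifItem(block, "_list_reference", default = NULL)
  if (!is.null(lr)) def$linkedParent <- tolower(lr[1])
  def
}

.ddl2Definition <- function(frame, typeRegexes, linkedPairs) {
  nm <- cifItem(frame, "_item.name", default = NULL)
  if (is.null(nm)) return(NULL)
  nm <- as.character(nm)
  def <- .defaultDefinition(nm[1])
  def$aliases <- nm[-1]
  al <- cifItem(frame, "_item_aliases.alias_name", default = NULL)
  if (!is.null(al)) def$aliases <- c(def$aliases, as.character(al))
  code <- cifItem(frame, "_item_type.code", default = NULL)
  if (!is.null(code)) {
    code <- tolower(code[1])
    def$dataType <- if (code %in% c("int", "float", "numb", "number")) "numb"
                    else code
    if (!is.null(typeRegexes[[code]])) def$typeRegex <- typeRegexes[[code]]
  }
  en <- cifItem(frame, "_item_enumeration.value", default = NULL)
  if (!is.null(en)) def$enumeration <- as.character(en)
  lo <- cifItem(frame, "_item_range.minimum", default = NULL)
  hi <- cifItem(frame, "_item_range.maximum", default = NULL)
  if (!is.null(lo) || !is.null(hi)) {
    lov <- suppressWarnings(as.numeric(lo)); hiv <- suppressWarnings(as.numeric(hi))
    def$range <- c(if (length(lov) && any(is.finite(lov))) min(lov, na.rm = TRUE) else NA_real_,
                   if (length(hiv) && any(is.finite(hiv))) max(hiv, na.rm = TRUE) else NA_real_)
  }
  mc <- cifItem(frame, "_item.mandatory_code", default = NULL)
  if (!is.null(mc)) def$mandatory <- tolower(mc[1]) == "yes"
  parent <- linkedPairs$parent[match(tolower(def$name), linkedPairs$child)]
  if (length(parent) && !is.na(parent)) def$linkedParent <- parent
  # mmCIF expresses uncertainties in separate _esd items; the parenthesis
  # convention is not policed for DDL2-typed values
  def$suAllowed <- TRUE
  def
}

.collectLinkedPairs <- function(block) {
  childCol <- parentCol <- character(0)
  harvest <- function(b) {
    ch <- cifItem(b, "_item_linked.child_name", default = NULL)
    pa <- cifItem(b, "_item_linked.parent_name", default = NULL)
    if (!is.null(ch) && !is.null(pa) && length(ch) == length(pa)) {
      childCol <<- c(childCol, tolower(as.character(ch)))
      parentCol <<- c(parentCol, tolower(as.character(pa)))
    }
  }
  harvest(block)
  for (fr in block@frames) harvest(fr)
  list(child = childCol, parent = parentCol)
}

#' Load a CIF data dictionary (DDL1 or DDL2)
#'
#' The source may be a local file path, literal CIF text (anything
#' containing a newline), a parsed [CifDocument-class], a URL, or a register
#' key resolved through a pluggable resolver. URL/register sources are
#' disabled unless a resolver is configured via
#' `options(cifio.dictionaryResolver = function(source) path_or_text)`, so
#' the package loads dictionaries with no network access by default.
#'
#' The DDL version is auto-detected: definitions carried in save frames with
#' pointed `_item.name` attributes mean DDL2; definitions carried in data
#' blocks with `_name` mean DDL1.
#'
#' @param source path, CIF text, document, URL or register key.
#' @return a [CifDictionary-class].
#' @export
loadDictionary <- function(source) {
  doc <- NULL
  if (is(source, "CifDocument")) doc <- source
  else {
    stopifnot(is.character(source), length(source) == 1L)
    opts <- cifParseOptions(strict = FALSE, permitGlobalBlocks = TRUE)
    if (grepl("\n", source, fixed = TRUE)) doc <- parseCif(source, opts)
    else if (file.exists(source)) doc <- readCif(source, opts)
    else {
      resolver <- getOption("cifio.dictionaryResolver", NULL)
      if (is.null(resolver))
        stop("cannot resolve dictionary source '", source,
             "': not a file, and no cifio.dictionaryResolver is configured")
      resolved <- resolver(source)
      if (is(resolved, "CifDocument")) doc <- resolved
      else if (grepl("\n", resolved, fixed = TRUE))
        doc <- parseCif(resolved, opts)
      else doc <- readCif(resolved, opts)
    }
  }

  defs <- list()
  title <- NA_character_; version <- NA_character_
  hasFrames <- any(vapply(doc@blocks, function(b) length(b@frames) > 0L,
                          logical(1)))
  ddl2 <- FALSE
  if (hasFrames) {
    for (b in doc@blocks)
      for (fr in b@frames)
        if (hasCifItem(fr, "_item.name")) { ddl2 <- TRUE; break }
  }
  if (ddl2) {
    for (b in doc@blocks) {
      t2 <- cifItem(b, "_dictionary.title", default = NULL)
      v2 <- cifItem(b, "_dictionary.version", default = NULL)
      if (!is.null(t2)) title <- t2[1]
      if (!is.null(v2)) version <- v2[1]
      regexes <- list()
      codes <- cifItem(b, "_item_type_list.code", default = NULL)
      cons <- cifItem(b, "_item_type_list.construct", default = NULL)
      if (!is.null(codes) && !is.null(cons) && length(codes) == length(cons))
        regexes <- stats::setNames(as.list(as.character(cons)),
                                   tolower(as.character(codes)))
      linked <- .collectLinkedPairs(b)
      for (fr in b@frames) {
        def <- .ddl2Definition(fr, regexes, linked)
        if (!is.null(def)) defs[[tolower(def$name)]] <- def
      }
    }
    ddlVersion <- "ddl2"
  } else {
    for (b in doc@blocks) {
      t1 <- cifItem(b, "_dictionary_name", default = NULL)
      v1 <- cifItem(b, "_dictionary_version", default = NULL)
      if (!is.null(t1)) title <- t1[1]
      if (!is.null(v1)) version <- v1[1]
      def <- .ddl1Definition(b)
      if (!is.null(def)) defs[[tolower(def$name)]] <- def
    }
    ddlVersion <- "ddl1"
  }
  if (length(defs) == 0L)
    stop("dictionary contains zero definitions")
  new("CifDictionary", ddlVersion = ddlVersion, definitions = defs,
      title = as.character(title), version = as.character(version))
}

#' Look up a definition (by name or alias) in a dictionary
#'
#' @param dictionary a [CifDictionary-class].
#' @param name data name, case-insensitive.
#' @return the definition list, or `NULL`.
#' @export
dictDefinition <- function(dictionary, name) {
  canon <- tolower(name)
  def <- dictionary@definitions[[canon]]
  if (!is.null(def)) return(def)
  for (d in dictionary@definitions)
    if (canon %in% tolower(d$aliases)) return(d)
  NULL
}

setMethod("show", "CifDictionary", function(object) {
  cat(sprintf("CifDictionary '%s' version %s (%s): %d definitions\n",
              object@title, object@version, toupper(object@ddlVersion),
              length(object@definitions)))
})

#' @describeIn loadDictionary number of definitions.
#' @param x a [CifDictionary-class].
#' @export
setMethod("length", "CifDictionary", function(x) length(x@definitions))
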