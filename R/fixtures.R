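## Programmatic generators of test inputs: well-formed random documents
## exercising every quoting style, one malformed exemplar per common syntax
## error class, crystal-structure and reflection fixtures, and toy DDL1/DDL2
## dictionaries. All generators are pure functions of their arguments and a
## seed: the same call yields byte-identical output.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.randWord <- function(minLen = 3L, maxLen = 8L) {
  n <- sample(minLen:maxLen, 1)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

## one random raw value of a given style
.randValue <- function(style) {
  switch(style,
    plain = sample(c(.randWord(), sprintf("%.3f", runif(1, -50, 50)),
                     sprintf("%.4f(%d)", runif(1), sample(1:9, 1)),
                     as.character(sample(-100:100, 1))), 1),
    whitespace = paste(replicate(sample(2:4, 1), .randWord()), collapse = " "),
    bracket = paste0("[", .randWord(), "]"),
    squote = paste0(.randWord(), "'", .randWord()),
    dquote = paste0(.randWord(), "\"", .randWord()),
    multiline = paste(replicate(sample(2:4, 1), .randWord()), collapse = "\n"),
    bothquotes = paste0(.randWord(), "' \"", .randWord(), "\" '", .randWord()),
    reservedish = paste0("_", .randWord()),
    marker = sample(c("?", ".", ""), 1))
}

.VALUE_STYLES <- c("plain", "plain", "plain", "whitespace", "bracket",
                   "squote", "dquote", "multiline", "bothquotes",
                   "reservedish", "marker")

#' Generate a random well-formed CIF document
#'
#' The document exercises every quoting style the writer supports: plain
#' tokens, whitespace strings, leading brackets, embedded single/double/both
#' quotes, multi-line text fields, underscore-leading strings and the
#' `?`/`.`/empty markers. Deterministic per seed.
#'
#' @param seed integer random seed.
#' @param nBlocks,nItems,nLoops,maxRows size controls (loops have 1..maxRows
#'   rows; a zero-row loop is not serializable unambiguously in CIF 1.1).
#' @return list with `document` (a [CifDocument-class]) and `text`
#'   (its serialized form).
#' @export
makeRandomDocument <- function(seed = 1L, nBlocks = 1L, nItems = 5L,
                               nLoops = 1L, maxRows = 5L) {
  stopifnot(nBlocks >= 0L, nItems >= 0L, nLoops >= 0L, maxRows >= 1L)
  .withSeed(seed, {
    blocks <- list()
    usedBlockNames <- character(0)
    for (bi in seq_len(nBlocks)) {
      repeat {
        bname <- paste0(.randWord(), bi)
        if (!tolower(bname) %in% tolower(usedBlockNames)) break
      }
      usedBlockNames <- c(usedBlockNames, bname)
      blk <- cifBlock(bname)
      used <- character(0)
      newTag <- function(cat) {
        repeat {
          tg <- paste0("_", cat, "_", .randWord())
          if (!tolower(tg) %in% used) { used <<- c(used, tolower(tg)); return(tg) }
        }
      }
      cat1 <- .randWord()
      for (ii in seq_len(nItems)) {
        style <- sample(.VALUE_STYLES, 1)
        blk <- setCifItem(blk, newTag(cat1), .randValue(style))
      }
      for (li in seq_len(nLoops)) {
        catL <- .randWord()
        ncol <- sample(2:4, 1)
        tags <- vapply(seq_len(ncol), function(i) newTag(catL), character(1))
        nr <- sample(seq_len(maxRows), 1)
        rows <- lapply(seq_len(nr), function(r)
          vapply(seq_len(ncol), function(cc)
            .randValue(sample(setdiff(.VALUE_STYLES, "multiline"), 1)),
            character(1)))
        blk <- addLoop(blk, tags, rows)
      }
      blocks[[bname]] <- blk
    }
    doc <- cifDocument(blocks)
    list(document = doc, text = writeCif(doc))
  })
}

#' Generate a malformed CIF exemplifying one syntax error class
#'
#' Parsed leniently, the returned text yields at least one diagnostic of
#' exactly the requested class; parsed strictly, it raises.
#'
#' @param errorClass integer 1..12 (see [cifErrorClasses()]).
#' @param seed integer; varies incidental names/values only.
#' @return list with `text`, `errorClass`, `description` and `line` (the
#'   line carrying the defect, `NA` for the loop-scoped class 11 where the
#'   finding names the loop rather than a line).
#' @export
makeMalformed <- function(errorClass, seed = 1L) {
  stopifnot(errorClass %in% 1:12)
  .withSeed(seed, {
    w <- .randWord()
    spec <- switch(as.character(errorClass),
      "1" = list(text = sprintf("data_%s\n_a 'abc\n_b 2\n", w), line = 2L),
      "2" = list(text = sprintf("data_%s\n_a 'two words\n_b 2\n", w), line = 2L),
      "3" = list(text = sprintf("stray preamble text\ndata_%s\n_a 1\n", w),
                 line = 1L),
      "4" = list(text = sprintf("data_%s\n_a\n;\nnever closed\n", w), line = 3L),
      "5" = list(text = sprintf("data_%s\n_a 1 2\n_b 3\n", w), line = 2L),
      "6" = list(text = sprintf("data_%s\n_a\n_b 2\n", w), line = 2L),
      "7" = list(text = "_a 1\n_b 2\n", line = 1L),
      "8" = list(text = sprintf("data_my file%s\n_a 1\n", w), line = 1L),
      "9" = list(text = sprintf("data_%s\n_name 'Jos\xe9'\n_b 2\n", w),
                 line = 2L),
      "10" = list(text = sprintf("data_%s\n_a [abc]\n_b 2\n", w), line = 2L),
      "11" = list(text = sprintf("data_%s\nloop_\n_x_u\n_x_v\n1 2 3\n_b 4\n", w),
                  line = NA_integer_),
      "12" = list(text = sprintf("global_\n_t 5\ndata_%s\n_u 6\n", w),
                  line = 1L))
    txt <- spec$text
    if (errorClass == 9L) Encoding(txt) <- "latin1"
    list(text = txt, errorClass = as.integer(errorClass),
         description = unname(cifErrorClasses()[as.character(errorClass)]),
         line = spec$line)
  })
}

#' Generate a random crystal structure in one of the bundled space groups
#'
#' Cell parameters are drawn per crystal system (triclinic for P1/P-1,
#' monoclinic b-unique for P2_1/c), coordinates are uniform in the cell and
#' rounded to 4 decimals with standard uncertainties of a few parts in 1e4
#' -- typical of a routine small-molecule refinement. Deterministic per
#' seed.
#'
#' @param group "P1", "P-1" or "P2_1/c".
#' @param nSites number of atomic sites.
#' @param seed integer random seed.
#' @param aniso logical; attach anisotropic displacement tensors.
#' @return a [CrystalStructure-class].
#' @export
makeStructureFixture <- function(group = c("P1", "P-1", "P2_1/c"),
                                 nSites = 3L, seed = 1L, aniso = FALSE) {
  group <- match.arg(group)
  .withSeed(seed, {
    monoclinic <- group == "P2_1/c"
    len <- round(runif(3, 5, 15), 4)
    ang <- if (monoclinic) c(90, round(runif(1, 95, 110), 3), 90)
           else round(runif(3, 80, 100), 3)
    cellSu <- c(round(runif(3, 1, 9)) * 1e-4,
                if (monoclinic) c(NA, round(runif(1, 1, 9)) * 1e-3, NA)
                else round(runif(3, 1, 9)) * 1e-3)
    cell <- unitCell(len[1], len[2], len[3], ang[1], ang[2], ang[3],
                     su = cellSu)
    ops <- spaceGroupSymops(group)
    elements <- c("C", "N", "O", "S")
    n <- nSites
    sym <- sample(elements, n, replace = TRUE)
    sites <- data.frame(
      label = paste0(sym, seq_len(n)),
      symbol = sym,
      x = round(runif(n), 4), y = round(runif(n), 4), z = round(runif(n), 4),
      occ = 1,
      uiso = round(runif(n, 0.01, 0.08), 4),
      suX = sample(1:9, n, replace = TRUE) * 1e-4,
      suY = sample(1:9, n, replace = TRUE) * 1e-4,
      suZ = sample(1:9, n, replace = TRUE) * 1e-4,
      suUiso = sample(1:9, n, replace = TRUE) * 1e-4,
      stringsAsFactors = FALSE)
    if (aniso) {
      for (fld in c("u11", "u22", "u33"))
        sites[[fld]] <- round(runif(n, 0.01, 0.08), 4)
      for (fld in c("u12", "u13", "u23"))
        sites[[fld]] <- round(runif(n, -0.01, 0.01), 4)
      for (fld in c("suU11", "suU22", "suU33", "suU12", "suU13", "suU23"))
        sites[[fld]] <- sample(1:9, n, replace = TRUE) * 1e-4
    }
    crystalStructure(cell, ops, sites,
                     spaceGroupSymbol = sub("_", "", group))
  })
}

#' Generate a random reflection set (fcf-style content)
#'
#' Unique Miller indices in a +-5 cube (never (0,0,0)), measured F-squared
#' values with counting-statistics-like sigmas, and a few missing ('?')
#' measurements. Deterministic per seed.
#'
#' @param n number of reflections.
#' @param seed integer random seed.
#' @param missingFraction fraction of measurements replaced by NA
#'   (serialized as '?').
#' @return a [ReflectionSet-class].
#' @export
makeReflectionFixture <- function(n = 100L, seed = 1L,
                                  missingFraction = 0.05) {
  .withSeed(seed, {
    grid <- expand.grid(h = -5:5, k = -5:5, l = -5:5)
    grid <- grid[rowSums(abs(grid)) > 0, ]
    stopifnot(n <= nrow(grid))
    idx <- as.matrix(grid[sample(nrow(grid), n), ])
    f2 <- round(abs(stats::rnorm(n, 50, 40)), 2)
    sig <- round(0.5 + sqrt(pmax(f2, 0.1)) * 0.2, 2)
    miss <- stats::runif(n) < missingFraction
    f2[miss] <- NA
    fc <- round(abs(stats::rnorm(n, 50, 40)), 2)
    cell <- unitCell(round(runif(1, 6, 12), 4), round(runif(1, 6, 12), 4),
                     round(runif(1, 6, 12), 4))
    reflectionSet(idx, data = list(F_squared_meas = f2, F_squared_calc = fc),
                  sigmas = list(F_squared_meas = sig), cell = cell,
                  symops = list(symOp()))
  })
}

#' Toy DDL1 and DDL2 dictionaries for validation tests
#'
#' `toyDdl1Dictionary()` defines six core-style items in the `_toy_`
#' namespace: `_toy_count` (numb, >= 0), `_toy_color` (char, enumeration
#' red/green), `_toy_site_label` (char, must loop), `_toy_name` (char, must
#' not loop), `_toy_length` (numb, su allowed) and `_toy_site_occupancy`
#' (numb in [0,1], looped, linked to `_toy_site_label`).
#' `toyDdl2Dictionary()` defines pointed `_toy.` analogues in save frames
#' with an int/float type list.
#'
#' @return CIF dictionary text (character scalar) suitable for
#'   [loadDictionary()].
#' @export
toyDdl1Dictionary <- function() {
  paste0(
    "data_on_this_dictionary\n",
    "_dictionary_name toy_core.dic\n",
    "_dictionary_version 1.0\n",
    "data_toy_count\n",
    "_name '_toy_count'\n",
    "_category toy\n",
    "_type numb\n",
    "_enumeration_range 0:\n",
    "_list no\n",
    "data_toy_color\n",
    "_name '_toy_color'\n",
    "_category toy\n",
    "_type char\n",
    "loop_\n_enumeration\n red\n green\n",
    "data_toy_site_label\n",
    "_name '_toy_site_label'\n",
    "_category toy_site\n",
    "_type char\n",
    "_list yes\n",
    "data_toy_name\n",
    "_name '_toy_name'\n",
    "_category toy\n",
    "_type char\n",
    "_list no\n",
    "data_toy_length\n",
    "_name '_toy_length'\n",
    "_category toy\n",
    "_type numb\n",
    "_type_conditions esd\n",
    "_enumeration_range 0:\n",
    "_list no\n",
    "data_toy_site_occupancy\n",
    "_name '_toy_site_occupancy'\n",
    "_category toy_site\n",
    "_type numb\n",
    "_enumeration_range 0:1\n",
    "_list yes\n",
    "_list_reference '_toy_site_label'\n")
}

#' @rdname toyDdl1Dictionary
#' @export
toyDdl2Dictionary <- function() {
  paste0(
    "data_toy_ddl2.dic\n",
    "_dictionary.title toy_ddl2\n",
    "_dictionary.version 1.0\n",
    "loop_\n_item_type_list.code\n_item_type_list.construct\n",
    " int '[+-]?[0-9]+'\n",
    " float '[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?(\\([0-9]+\\))?'\n",
    " code '[^ \\t]+'\n",
    "save__toy.count\n",
    "_item.name '_toy.count'\n",
    "_item.category_id toy\n",
    "_item.mandatory_code no\n",
    "_item_type.code int\n",
    "loop_\n_item_range.minimum\n_item_range.maximum\n 0 .\n",
    "save_\n",
    "save__toy.color\n",
    "_item.name '_toy.color'\n",
    "_item.category_id toy\n",
    "_item.mandatory_code no\n",
    "_item_type.code code\n",
    "loop_\n_item_enumeration.value\n red\n green\n",
    "save_\n",
    "save__toy.site_id\n",
    "_item.name '_toy.site_id'\n",
    "_item.category_id toy_site\n",
    "_item.mandatory_code yes\n",
    "_item_type.code code\n",
    "save_\n",
    "save__toy.site_occupancy\n",
    "_item.name '_toy.site_occupancy'\n",
    "_item.category_id toy_site\n",
    "_item.mandatory_code no\n",
    "_item_type.code float\n",
    "loop_\n_item_linked.child_name\n_item_linked.parent_name\n",
    " '_toy.site_occupancy' '_toy.site_id'\n",
    "save_\n")
}

#' Dump the full fixture corpus to a directory
#'
#' Writes one file per malformed class (`malformed_class_NN.cif`), a set of
#' well-formed random documents, one structure and one reflection fixture,
#' and the two toy dictionaries.
#'
#' @param dir output directory (created if needed).
#' @param seed integer random seed.
#' @param nWellFormed number of random well-formed documents.
#' @return invisibly, the character vector of files written.
#' @export
fixtureCorpus <- function(dir, seed = 1L, nWellFormed = 5L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(name, text) {
    path <- file.path(dir, name)
    con <- file(path, open = "wb")
    writeBin(charToRaw(text), con)
    close(con)
    files <<- c(files, path)
  }
  for (cls in 1:12)
    put(sprintf("malformed_class_%02d.cif", cls),
        makeMalformed(cls, seed = seed)$text)
  for (i in seq_len(nWellFormed))
    put(sprintf("wellformed_%02d.cif", i),
        makeRandomDocument(seed = seed + i)$text)
  put("structure_p21c.cif",
      writeCif(cifDocument(list(s = structureAsCif(
        makeStructureFixture("P2_1/c", nSites = 4, seed = seed))))))
  put("reflections.cif",
      writeCif(cifDocument(list(r = reflectionsAsCif(
        makeReflectionFixture(n = 100, seed = seed))))))
  put("toy_ddl1.dic", toyDdl1Dictionary())
  put("toy_ddl2.dic", toyDdl2Dictionary())
  invisible(files)
}
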