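## CIF numeric convention: a value such as "10.232(3)" carries a standard
## uncertainty in parentheses, scaled to the last decimal place of the
## mantissa. "?" means unknown, "." means inapplicable. Interpretation is
## always on demand; the model stores raw strings.

.cifNumberRe <- "^([+-]?)(([0-9]+)(\\.([0-9]*))?|\\.([0-9]+))([eE]([+-]?[0-9]+))?(\\(([0-9]+)\\))?$"

#' Interpret one CIF value string under the CIF numeric convention
#'
#' @param raw a single CIF value token (character scalar).
#' @return a list with elements `raw`, `semantic` (one of "number",
#'   "string", "unknown", "inapplicable"), `number` (decimal value or `NA`)
#'   and `su` (standard uncertainty derived from trailing parenthesized
#'   digits, or `NA`). Unparseable numerics fall back to `semantic =
#'   "string"`; the function never fails.
#'
#' @examples
#' parseCifNumber("12.34(5)")   # number 12.34, su 0.05
#' parseCifNumber("?")          # unknown
#' parseCifNumber("-1.2e1")     # number -12
#' @export
parseCifNumber <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  out <- list(raw = raw, semantic = "string", number = NA_real_, su = NA_real_)
  if (identical(raw, "?")) { out$semantic <- "unknown"; return(out) }
  if (identical(raw, ".")) { out$semantic <- "inapplicable"; return(out) }
  m <- regmatches(raw, regexec(.cifNumberRe, raw))[[1]]
  if (length(m) == 0L) return(out)
  sign <- if (identical(m[2], "-")) -1 else 1
  mantissa <- m[3]
  expo <- if (nzchar(m[9])) as.numeric(m[9]) else 0
  suDigits <- m[11]
  value <- sign * as.numeric(mantissa) * 10^expo
  if (!is.finite(value)) return(out)
  out$semantic <- "number"
  out$number <- value
  if (nzchar(suDigits)) {
    # su counts in units of the mantissa's last decimal place, then the
    # exponent applies to both.
    frac <- if (nzchar(m[6])) m[6] else m[7]   # digits after the point
    nDec <- nchar(frac)
    out$su <- as.numeric(suDigits) * 10^(-nDec + expo)
  }
  out
}

#' Vectorized numeric interpretation of CIF value strings
#'
#' @param x character vector of raw CIF values.
#' @return data.frame with columns `value`, `su`, `semantic`; `value` is `NA`
#'   for "?"/"."/non-numeric strings.
#' @export
parseCifNumbers <- function(x) {
  res <- lapply(x, parseCifNumber)
  data.frame(value = vapply(res, `[[`, numeric(1), "number"),
             su = vapply(res, `[[`, numeric(1), "su"),
             semantic = vapply(res, `[[`, character(1), "semantic"),
             stringsAsFactors = FALSE)
}

#' Render a number with its standard uncertainty in parenthesis notation
#'
#' Chooses the number of decimal places so that the uncertainty is an
#' integer count of the last decimal place, e.g. `formatNumberSu(10.232,
#' 0.003)` gives `"10.232(3)"`. With `su = NA` the value is formatted alone
#' with up to 15 significant digits (exact for values that originated from
#' short decimals).
#'
#' @param value numeric scalar.
#' @param su standard uncertainty or `NA`.
#' @return character scalar.
#' @export
formatNumberSu <- function(value, su = NA_real_) {
  stopifnot(is.numeric(value), length(value) == 1L)
  if (!is.finite(value)) return(if (is.na(value)) "?" else as.character(value))
  if (!length(su) || is.na(su) || su <= 0)
    return(format(value, digits = 15, scientific = FALSE, trim = TRUE))
  k <- NA_integer_
  for (kk in 0:12) {
    s <- su * 10^kk
    if (abs(s - round(s)) < 1e-9 * max(1, s) && round(s) >= 1) { k <- kk; break }
  }
  if (is.na(k)) {
    # not an exact multiple of a decimal place: use two significant su digits
    k <- max(0L, as.integer(ceiling(-log10(su)) + 1L))
  }
  digits <- as.integer(round(su * 10^k))
  paste0(formatC(value, format = "f", digits = k), "(", digits, ")")
}
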