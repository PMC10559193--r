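# Shared low-level helpers: tokenisation, span arithmetic, rounding.
#
# All character spans in this package are 0-based half-open intervals over the
# original string, so `span_str(x, start, end)` == the matched substring and
# spans compose under concatenation by simple offset shifts.

#' Extract the substring covered by a 0-based half-open span
#'
#' @param x Character scalar.
#' @param start,end Integer span, 0-based half-open.
#' @return Character vector of substrings.
#' @export
span_str <- function(x, start, end) {
  substring(x, start + 1L, end)
}

# Tokens are maximal runs of alphanumerics; a hyphen joining two alphanumeric
# runs is word-internal ("post-traumatic" is one token, so the bare term
# "alcohol" does not match inside "alcohol-involved").
tm_token_regex <- "[[:alnum:]]+(?:-[[:alnum:]]+)*"

#' Tokenize text with character offsets
#'
#' @param text Character scalar.
#' @return A data.frame with columns `token`, `start`, `end` (0-based
#'   half-open spans into `text`).
#' @keywords internal
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr(tm_token_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(
    token = substring(text, start + 1L, end),
    start = start, end = end,
    stringsAsFactors = FALSE
  )
}

#' Round half away from zero at a fixed number of decimal places
#'
#' Commercial ("half-up") rounding, the convention used for all reported
#' percentages; `round()`'s banker's rounding would disagree on exact halves.
#' A tiny epsilon absorbs binary representation error such as
#' `100 * 47 / 91` sitting a hair below the stored decimal.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (scalar or vector recycled against `x`).
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage with reporting-style rounding
#'
#' @param count,denominator Numerators and denominators.
#' @param digits Decimal places to report.
#' @return `round_half_up(100 * count / denominator, digits)`; `NA` where the
#'   denominator is zero.
#' @examples
#' percent(1493, 11814)        # 12.64
#' percent(47, 91, digits = 0) # 52
#' @export
percent <- function(count, denominator, digits = 2) {
  out <- round_half_up(100 * count / denominator, digits)
  out[denominator == 0] <- NA_real_
  out
}

# stopifnot-with-message helper
tm_assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}
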