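# Sentence segmentation. Extraction is sentence-focused: anchors never license
# terms across a sentence boundary, so segmentation errors bound the scope of
# every rule.

# words whose trailing period is not a sentence boundary
.tm_abbrev <- c(
  "e.g", "eg", "i.e", "ie", "vs", "cf", "etc", "al", "et",
  "dr", "mr", "mrs", "ms", "prof", "st", "jr", "sr",
  "fig", "figs", "no", "nos", "approx", "ca", "resp"
)

#' Split text into sentences
#'
#' Splits at runs of `.`, `!` or `?` that are followed by whitespace and a
#' capital letter or digit. A trailing period after a known abbreviation
#' (`"e.g."`, `"vs."`, `"Dr."`, ...) or after a single letter (initials) is not
#' a boundary, and decimals (`"4.5 per 100"`) never split because no
#' whitespace follows the period.
#'
#' @param text Character scalar.
#' @return A tibble with one row per sentence: `index` (1-based), `text`
#'   (with surrounding whitespace trimmed), `start`, `end` (0-based half-open
#'   span of the trimmed sentence in `text`). Sentences are disjoint and
#'   ordered.
#' @examples
#' split_sentences("A study. Of prisoners.")
#' split_sentences("Prevalence was 4.5 per 100.")
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble(index = integer(), text = character(),
                  start = integer(), end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  m <- gregexpr("[.!?]+(?=[[:space:]]+[\"'(]?[A-Z0-9])", text, perl = TRUE)[[1]]
  cuts <- integer()
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L # last punct char, 1-based
    for (k in seq_along(ends)) {
      punct <- substring(text, as.integer(m)[k], ends[k])
      if (grepl("[!?]", punct)) {
        cuts <- c(cuts, ends[k])
        next
      }
      before <- substring(text, 1L, as.integer(m)[k] - 1L)
      word <- regmatches(before, regexpr("[A-Za-z.]+$", before))
      w <- if (length(word)) tolower(sub("\\.+$", "", word)) else ""
      if (nchar(w) == 1L || w %in% .tm_abbrev) next
      cuts <- c(cuts, ends[k])
    }
  }
  bounds <- c(0L, cuts, nchar(text)) # 0-based half-open segment ends
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    s0 <- bounds[k]
    e0 <- bounds[k + 1L]
    seg <- substring(text, s0 + 1L, e0)
    lead <- nchar(seg) - nchar(sub("^[[:space:]]+", "", seg))
    trail <- nchar(seg) - nchar(sub("[[:space:]]+$", "", seg))
    s0 <- s0 + lead
    e0 <- e0 - trail
    if (e0 <= s0) next
    out[[length(out) + 1L]] <- data.frame(
      text = span_str(text, s0, e0), start = s0, end = e0,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  df <- do.call(rbind, out)
  tibble(index = seq_len(nrow(df)), text = df$text,
         start = df$start, end = df$end)
}
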