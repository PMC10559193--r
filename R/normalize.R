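# Theme standardization and abstract-level unification: synonym/acronym
# mentions collapse to one canonical theme label per abstract, so all
# downstream counting is at the abstract level.

#' Standardize surface themes to canonical labels
#'
#' Maps a surface term (as matched in text) to its canonical theme label via
#' the lexicon, e.g. `"AIDS"` to `"HIV"` and `"depressive disorder"` to
#' `"depression"`. Standardizing a canonical label returns itself (the lexicon
#' guarantees self-mapping closure), so the operation is idempotent.
#'
#' @param x Character vector of surface terms or canonical labels.
#' @param lex A `theme_lexicon`.
#' @return Character vector of canonical labels.
#' @examples
#' lex <- default_lexicon()
#' standardize_theme(c("AIDS", "HIV", "depressive disorder"), lex)
#' @export
standardize_theme <- function(x, lex) {
  stopifnot(inherits(lex, "theme_lexicon"))
  x <- trimws(gsub("[[:space:]]+", " ", as.character(x)))
  fold <- lex$entries$fold
  hit <- match(x, fold)
  miss <- is.na(hit)
  hit[miss] <- match(tolower(x[miss]), fold)
  if (anyNA(hit)) {
    stop("surface term(s) absent from the lexicon: ",
         paste(unique(x[is.na(hit)]), collapse = ", "), call. = FALSE)
  }
  lex$entries$canonical[hit]
}

#' Unify mentions into an abstract-level theme set
#'
#' Standardizes each mention and removes duplicate themes, yielding the set of
#' distinct canonical themes studied in one abstract. `mention_count` keeps
#' the pre-deduplication tally, so `length(themes) <= mention_count` always.
#' The result is invariant to mention order and idempotent under
#' re-application.
#'
#' @param mentions A mention tibble from [extract_mentions()] (all from one
#'   abstract), or a character vector of surface terms.
#' @param lex A `theme_lexicon`.
#' @return A list with `themes` (character vector of distinct canonical
#'   labels, in order of first occurrence) and `mention_count` (integer).
#' @examples
#' lex <- default_lexicon()
#' unify_mentions(c("HPC", "hepatitis C", "HIV"), lex)
#' @export
unify_mentions <- function(mentions, lex) {
  surfaces <- if (is.data.frame(mentions)) {
    # prefer the already-standardized canonical column when present
    if ("canonical" %in% names(mentions)) mentions$canonical else mentions$surface_text
  } else {
    as.character(mentions)
  }
  if (!length(surfaces)) {
    return(list(themes = character(), mention_count = 0L))
  }
  std <- standardize_theme(surfaces, lex)
  list(themes = unique(std), mention_count = length(surfaces))
}
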