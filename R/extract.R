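# End-to-end corpus extraction: records -> mentions -> unified abstract-level
# theme sets, with country and income-group metadata attached, plus the
# themes-TSV interchange format used by the CLI and the aggregation module.

#' Extract unified themes for a whole corpus
#'
#' Runs [extract_mentions()] and [unify_mentions()] over every record and
#' attaches country ([extract_countries()]) and income group
#' ([classify_income()]) from the first author's affiliation.
#'
#' @param records A record tibble from [parse_medline()] (typically the
#'   `kept` component of [filter_corpus()]).
#' @param rules A `theme_rules` object.
#' @param lex A `theme_lexicon`.
#' @param income An `income_table` (or `NULL` to skip affiliation handling).
#' @return A tibble with one row per abstract: `pmid`, `year`, `country`
#'   (first recognized country or `""`), `income_group`, `themes`
#'   (list-column of canonical labels), `mention_count`.
#' @export
extract_corpus <- function(records, rules = default_rules(),
                           lex = default_lexicon(),
                           income = default_income_table()) {
  stopifnot(is.data.frame(records))
  tm_assert(!anyDuplicated(records$pmid), "duplicate pmid(s) in corpus")
  mentions <- lapply(records$text, extract_mentions, rules = rules, lex = lex)
  unified <- lapply(mentions, unify_mentions, lex = lex)
  if (!is.null(income)) {
    countries <- extract_countries(records$affiliation, income)
    group <- suppressWarnings(classify_income(countries, income))
    country <- vapply(countries, function(cc) if (length(cc)) cc[1] else "",
                      character(1))
  } else {
    country <- rep("", nrow(records))
    group <- rep("unknown", nrow(records))
  }
  tibble(
    pmid = records$pmid,
    year = records$year,
    country = country,
    income_group = group,
    themes = lapply(unified, `[[`, "themes"),
    mention_count = vapply(unified, `[[`, integer(1), "mention_count")
  )
}

#' Write corpus themes as TSV
#'
#' Interchange format: `pmid	year	country	income_group	themes`, the
#' theme set semicolon-joined, one row per abstract.
#'
#' @param corpus_themes Output of [extract_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_themes <- function(corpus_themes, path) {
  df <- data.frame(
    pmid = corpus_themes$pmid,
    year = corpus_themes$year,
    country = corpus_themes$country,
    income_group = corpus_themes$income_group,
    themes = vapply(corpus_themes$themes, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read corpus themes from TSV
#'
#' @param path A file written by [write_themes()].
#' @return A tibble matching [extract_corpus()] output (without
#'   `mention_count`, which the interchange format does not carry).
#' @export
read_themes <- function(path) {
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   colClasses = "character")
  tm_assert(all(c("pmid", "year", "themes") %in% names(df)),
            "themes file needs columns pmid, year, themes: ", path)
  tibble(
    pmid = df$pmid,
    year = suppressWarnings(as.integer(df$year)),
    country = if ("country" %in% names(df)) df$country else "",
    income_group = if ("income_group" %in% names(df)) df$income_group else "unknown",
    themes = lapply(strsplit(df$themes, ";", fixed = TRUE),
                    function(x) x[nzchar(x)])
  )
}
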