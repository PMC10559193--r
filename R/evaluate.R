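# Abstract-level evaluation against gold annotations. The unit of scoring is
# the standardized theme within one abstract: detecting any mention of a gold
# theme is one true positive for that (abstract, theme) pair, an extracted
# theme absent from the gold set is a false positive, and an unextracted gold
# theme is a false negative. Precision/recall/F1 follow their standard
# definitions; the inter-annotator statistic is the raw (absolute) agreement
# rate, not a chance-corrected coefficient.

#' Score one abstract against its gold annotation
#'
#' Set semantics over standardized theme labels: `tp = |pred n gold|`,
#' `fp = |pred \\ gold|`, `fn = |gold \\ pred|`. Partial mention detection is
#' already credited upstream by unification, so finding one of several
#' mentions of a theme still yields `tp = 1` for that theme.
#'
#' @param pred Character vector of predicted canonical themes (duplicates
#'   ignored).
#' @param gold Character vector of gold canonical themes.
#' @param pmid Optional pair of identifiers; if both are given they must
#'   match.
#' @return Named integer vector `c(tp =, fp =, fn =)`.
#' @examples
#' score_abstract(c("hepatitis C"), c("hepatitis C")) # tp 1
#' score_abstract(c("A", "C"), c("A", "B"))           # tp 1, fp 1, fn 1
#' @export
score_abstract <- function(pred, gold, pmid = NULL) {
  if (!is.null(pmid) && length(pmid) == 2L) {
    tm_assert(identical(as.character(pmid[1]), as.character(pmid[2])),
              "pmid mismatch between prediction and gold: ",
              pmid[1], " vs ", pmid[2])
  }
  p <- unique(as.character(pred))
  g <- unique(as.character(gold))
  c(tp = length(intersect(p, g)),
    fp = length(setdiff(p, g)),
    fn = length(setdiff(g, p)))
}

.safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Corpus-level precision, recall and F1
#'
#' Tallies [score_abstract()] over all abstracts. Micro-averaging (the
#' default) sums tp/fp/fn across abstracts and then forms the ratios;
#' macro-averaging computes per-abstract precision and recall and averages
#' them (abstracts where a ratio is undefined are dropped from that average).
#' Undefined ratios (zero denominator) are reported as `NA`.
#'
#' @param preds,golds Tibbles with a `pmid` column and a `themes` list-column
#'   (e.g. [extract_corpus()] output and [read_gold()] output). The pmid sets
#'   must agree.
#' @param average `"micro"` (default) or `"macro"`.
#' @return An object of class `eval_report`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1` (proportions in `[0, 1]`), `n_abstracts`,
#'   `average`.
#' @export
corpus_metrics <- function(preds, golds, average = c("micro", "macro")) {
  average <- match.arg(average)
  tm_assert(setequal(preds$pmid, golds$pmid),
            "prediction and gold pmid sets differ")
  g <- golds$themes[match(preds$pmid, golds$pmid)]
  tallies <- t(mapply(function(p, gg) score_abstract(p, gg), preds$themes, g))
  tp <- sum(tallies[, "tp"]); fp <- sum(tallies[, "fp"]); fn <- sum(tallies[, "fn"])
  if (average == "micro") {
    precision <- .safe_ratio(tp, tp + fp)
    recall <- .safe_ratio(tp, tp + fn)
  } else {
    pr <- apply(tallies, 1, function(r) .safe_ratio(r["tp"], r["tp"] + r["fp"]))
    rc <- apply(tallies, 1, function(r) .safe_ratio(r["tp"], r["tp"] + r["fn"]))
    precision <- mean(pr, na.rm = TRUE)
    recall <- mean(rc, na.rm = TRUE)
    if (is.nan(precision)) precision <- NA_real_
    if (is.nan(recall)) recall <- NA_real_
  }
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1, n_abstracts = nrow(preds), average = average),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat("<eval_report> ", x$n_abstracts, " abstracts (", x$average, ")\n",
      "  tp=", x$tp, " fp=", x$fp, " fn=", x$fn, "\n",
      "  precision ", fmt(x$precision),
      "  recall ", fmt(x$recall),
      "  F1 ", fmt(x$f1), "\n", sep = "")
  invisible(x)
}

#' Absolute inter-annotator agreement rate
#'
#' For each abstract the judgement universe is the union of themes either
#' annotator marked; the agreement is the fraction of that union marked by
#' both. Abstract-level fractions are micro-averaged (summed intersections
#' over summed unions). Abstracts where both annotators marked nothing carry
#' no judgements; if that holds everywhere the rate is 1 by convention.
#'
#' @param ann1,ann2 Tibbles with `pmid` and a `themes` list-column, one per
#'   annotator, over the same pmid set.
#' @return A proportion in `[0, 1]`.
#' @examples
#' a1 <- tibble::tibble(pmid = "1", themes = list(c("A", "B")))
#' a2 <- tibble::tibble(pmid = "1", themes = list("A"))
#' absolute_agreement(a1, a2) # 0.5
#' @export
absolute_agreement <- function(ann1, ann2) {
  tm_assert(setequal(ann1$pmid, ann2$pmid), "annotator pmid sets differ")
  b <- ann2$themes[match(ann1$pmid, ann2$pmid)]
  inter <- mapply(function(x, y) length(intersect(unique(x), unique(y))),
                  ann1$themes, b)
  uni <- mapply(function(x, y) length(union(unique(x), unique(y))),
                ann1$themes, b)
  if (sum(uni) == 0) return(1)
  sum(inter) / sum(uni)
}

#' Read gold annotations
#'
#' Accepts either a TSV with header `pmid	theme` (one row per annotated
#' theme; an abstract with no themes may appear with an empty theme field) or
#' a JSON object `{"pmid": ["theme", ...], ...}`.
#'
#' @param path Path to the gold file.
#' @return A tibble with `pmid` and a `themes` list-column of distinct
#'   labels.
#' @export
read_gold <- function(path) {
  first <- trimws(readLines(path, n = 1L, warn = FALSE))
  if (startsWith(first, "{")) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    return(tibble(pmid = names(obj),
                  themes = lapply(obj, function(x) unique(as.character(x)))))
  }
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   colClasses = "character")
  tm_assert(all(c("pmid", "theme") %in% names(df)),
            "gold TSV needs columns pmid, theme: ", path)
  sets <- lapply(split(df$theme, df$pmid), function(x) unique(x[nzchar(x)]))
  tibble(pmid = names(sets), themes = unname(sets))
}

#' Write gold annotations as TSV
#'
#' @param gold A tibble with `pmid` and a `themes` list-column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(gold)), function(i) {
    th <- gold$themes[[i]]
    data.frame(pmid = gold$pmid[i],
               theme = if (length(th)) th else "",
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(pmid = character(), theme = character())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
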