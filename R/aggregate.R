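# Corpus analytics: theme and category frequency tables, annual proportion
# series, income-group breakdowns and the priority-vs-output gap report.
# Counting is always at the abstract level (an abstract with several distinct
# themes counts once per theme), and the corpus-wide denominator is the number
# of abstracts with at least one extracted theme. Percentages use half-up
# rounding at the reported precision (see percent()).

.themed <- function(corpus_themes) {
  corpus_themes[lengths(corpus_themes$themes) > 0, , drop = FALSE]
}

.freq_table <- function(labels_per_abstract, denominator, digits,
                        order_by = NULL) {
  counts <- table(unlist(labels_per_abstract))
  if (!length(counts)) {
    return(tibble(label = character(), count = integer(),
                  denominator = integer(), percent = numeric()))
  }
  df <- tibble(
    label = names(counts),
    count = as.integer(counts),
    denominator = as.integer(denominator),
    percent = percent(as.integer(counts), denominator, digits)
  )
  if (is.null(order_by)) {
    df[order(-df$count, df$label), ]
  } else {
    df[order(match(df$label, order_by)), ]
  }
}

#' Abstract-level theme frequencies
#'
#' Counts, per canonical theme, the number of abstracts mentioning it; an
#' abstract with several distinct themes contributes to each of them. The
#' denominator is the number of themed abstracts (at least one extracted
#' theme).
#'
#' @param corpus_themes A tibble with a `themes` list-column
#'   ([extract_corpus()] / [read_themes()] output).
#' @param digits Decimal places for the percent column (default 2).
#' @return A tibble `label`, `count`, `denominator`, `percent`, sorted by
#'   descending count.
#' @export
theme_frequencies <- function(corpus_themes, digits = 2) {
  themed <- .themed(corpus_themes)
  .freq_table(lapply(themed$themes, unique), nrow(themed), digits)
}

#' Category frequencies and within-category theme breakdown
#'
#' Abstract-level multi-label counts per priority category (an abstract
#' belongs to every category one of its themes maps to, once each), over the
#' themed-abstract denominator; plus, per category, the theme frequencies
#' with that category's abstract count as denominator.
#'
#' @param corpus_themes A tibble with a `themes` list-column.
#' @param scheme A `category_scheme`.
#' @param digits Decimal places (default 2).
#' @return A list with `categories` (one row per category in scheme order,
#'   including zero-count categories) and `themes_by_category` (columns
#'   `category`, `label`, `count`, `denominator`, `percent`).
#' @export
category_frequencies <- function(corpus_themes, scheme, digits = 2) {
  stopifnot(inherits(scheme, "category_scheme"))
  themed <- .themed(corpus_themes)
  cat_sets <- lapply(themed$themes, function(th) unique(map_theme(th, scheme)))
  cats <- .freq_table(cat_sets, nrow(themed), digits, order_by = scheme$categories)
  # include priority categories with zero output (needed for the gap report)
  missing <- setdiff(scheme$categories, cats$label)
  if (length(missing)) {
    cats <- rbind(cats, tibble(label = missing, count = 0L,
                               denominator = nrow(themed),
                               percent = percent(0, max(nrow(themed), 1), digits)))
    cats <- cats[order(match(cats$label, scheme$categories)), ]
  }
  by_cat <- lapply(seq_len(nrow(cats)), function(i) {
    cl <- cats$label[i]
    if (cats$count[i] == 0) return(NULL)
    sel <- vapply(cat_sets, function(cs) cl %in% cs, logical(1))
    th <- lapply(themed$themes[sel], function(t) unique(t[map_theme(t, scheme) == cl]))
    tab <- .freq_table(th, cats$count[i], digits)
    tab$category <- cl
    tab[c("category", "label", "count", "denominator", "percent")]
  })
  by_cat <- do.call(rbind, Filter(Negate(is.null), by_cat))
  if (is.null(by_cat)) {
    by_cat <- tibble(category = character(), label = character(),
                     count = integer(), denominator = integer(),
                     percent = numeric())
  }
  list(categories = cats, themes_by_category = as_tibble(by_cat))
}

#' Annual proportions of a theme or category
#'
#' For each year in `year_range`, the proportion of that year's themed
#' abstracts carrying each requested label. Labels are canonical themes, or
#' priority categories when a `scheme` is supplied. Years with no themed
#' abstracts get proportion 0 and are flagged.
#'
#' @param corpus_themes A tibble with `year` and a `themes` list-column.
#' @param labels Character vector of theme (or category) labels to trace.
#' @param year_range Length-2 integer vector `c(from, to)`; the series is
#'   contiguous over this range, zero-filled where empty.
#' @param scheme Optional `category_scheme`; when given, `labels` are
#'   categories.
#' @param digits Decimal places for the percent rendering (default 2).
#' @return A tibble `year`, `label`, `count`, `denominator`, `proportion`,
#'   `percent`, `zero_denominator`.
#' @export
annual_proportions <- function(corpus_themes, labels, year_range,
                               scheme = NULL, digits = 2) {
  tm_assert(length(year_range) == 2 && year_range[1] <= year_range[2],
            "year_range must be c(from, to)")
  themed <- .themed(corpus_themes)
  years <- seq.int(year_range[1], year_range[2])
  sets <- if (is.null(scheme)) {
    lapply(themed$themes, unique)
  } else {
    lapply(themed$themes, function(th) unique(map_theme(th, scheme)))
  }
  rows <- lapply(years, function(y) {
    in_year <- !is.na(themed$year) & themed$year == y
    den <- sum(in_year)
    cnt <- vapply(labels, function(lb) {
      sum(vapply(sets[in_year], function(s) lb %in% s, logical(1)))
    }, integer(1), USE.NAMES = FALSE)
    tibble(year = y, label = labels, count = cnt, denominator = den,
           proportion = ifelse(den > 0, cnt / den, 0),
           percent = ifelse(den > 0, percent(cnt, den, digits), 0),
           zero_denominator = den == 0)
  })
  do.call(rbind, rows)
}

#' Category distribution by country income group
#'
#' Per income group, the abstract-level category distribution with the group
#' size as denominator. Abstracts with unknown income group are excluded from
#' the four group denominators and reported as their own `"unknown"` rows.
#' `group_sizes` uses all themed abstracts (including unknown) as
#' denominator.
#'
#' @param corpus_themes A tibble with `income_group` and a `themes`
#'   list-column.
#' @param scheme A `category_scheme`.
#' @param digits Decimal places (default 2).
#' @return A list with `group_sizes` (`income_group`, `count`, `denominator`,
#'   `percent`) and `categories` (`income_group`, `category`, `count`,
#'   `denominator`, `percent`).
#' @export
income_breakdown <- function(corpus_themes, scheme, digits = 2) {
  stopifnot(inherits(scheme, "category_scheme"))
  themed <- .themed(corpus_themes)
  n_all <- nrow(themed)
  groups <- c("high", "upper-middle", "lower-middle", "low", "unknown")
  sizes <- vapply(groups, function(g) sum(themed$income_group == g),
                  integer(1), USE.NAMES = FALSE)
  group_sizes <- tibble(
    income_group = groups, count = sizes, denominator = n_all,
    percent = percent(sizes, max(n_all, 1), digits)
  )
  cat_rows <- lapply(groups, function(g) {
    sub <- themed[themed$income_group == g, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    cs <- lapply(sub$themes, function(th) unique(map_theme(th, scheme)))
    tab <- .freq_table(cs, nrow(sub), digits, order_by = scheme$categories)
    if (!nrow(tab)) return(NULL)
    tab$income_group <- g
    tab[c("income_group", "label", "count", "denominator", "percent")]
  })
  cats <- do.call(rbind, Filter(Negate(is.null), cat_rows))
  if (is.null(cats)) {
    cats <- tibble(income_group = character(), label = character(),
                   count = integer(), denominator = integer(),
                   percent = numeric())
  }
  names(cats)[names(cats) == "label"] <- "category"
  list(group_sizes = group_sizes, categories = as_tibble(cats))
}

#' Priority-vs-output gap report
#'
#' Joins the research-output rank of each priority category (by abstract
#' count) with the stakeholder priority rankings. A category a stakeholder
#' group ranked but with zero research output is flagged as a gap.
#'
#' @param category_freqs The `categories` table from
#'   [category_frequencies()] (columns `label`, `count`).
#' @param priority_rankings A tibble `category`, `stakeholder_group`,
#'   `priority_rank` (1 = highest priority).
#' @return A tibble `category`, `stakeholder_group`, `priority_rank`,
#'   `output_count`, `output_rank` (min-rank over descending count among the
#'   ranked categories), `rank_displacement` (`output_rank - priority_rank`),
#'   `gap` (logical).
#' @export
gap_report <- function(category_freqs, priority_rankings) {
  if (!nrow(priority_rankings)) {
    return(tibble(category = character(), stakeholder_group = character(),
                  priority_rank = integer(), output_count = integer(),
                  output_rank = integer(), rank_displacement = integer(),
                  gap = logical()))
  }
  counts <- setNames(category_freqs$count, category_freqs$label)
  out <- priority_rankings
  out$output_count <- as.integer(counts[out$category])
  out$output_count[is.na(out$output_count)] <- 0L
  # rank within each stakeholder group's ranked categories
  out <- do.call(rbind, lapply(split(out, out$stakeholder_group), function(g) {
    g$output_rank <- as.integer(rank(-g$output_count, ties.method = "min"))
    g
  }))
  rownames(out) <- NULL
  out$rank_displacement <- out$output_rank - as.integer(out$priority_rank)
  out$gap <- out$output_count == 0L
  as_tibble(out[order(out$stakeholder_group, out$priority_rank), ])
}

#' Published reporting-arithmetic fixtures
#'
#' The (count, denominator, printed percent) triples from the source corpus
#' report whose printed percent is exactly reproduced by [percent()] at the
#' printed precision. Used to validate the half-up rounding convention; see
#' the file header of `reported_percentages.tsv` for why a minority of the
#' published figures are omitted.
#'
#' @return A tibble `label`, `count`, `den`, `digits`, `printed`.
#' @export
reported_percentages <- function() {
  lines <- readLines(tm_file("reported_percentages.tsv"), encoding = "UTF-8",
                     warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*#", lines)]
  as_tibble(read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                       stringsAsFactors = FALSE))
}
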