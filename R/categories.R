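# Mapping standardized themes to stakeholder research-priority categories.
# The scheme is curated data: the ranked categories come from stakeholder
# priority setting (incarcerated people and prison health service directors),
# plus six catch-all categories created for themes outside those priorities
# ("Justice system", "Biomedical related", "Offense related", "Juveniles",
# "Behavior") and the fallback "Other". Categories with no mapped theme (e.g.
# hygiene, disability) are kept in the scheme: representing zero-output
# priorities is what makes the gap analysis possible.

#' Construct a category scheme
#'
#' @param categories Ordered character vector of category labels; must end
#'   with `"Other"` (appended if absent). Order defines report order.
#' @param assignments Named character vector or two-column data.frame
#'   (`theme`, `category`) mapping each canonical theme to exactly one
#'   category.
#' @return An object of class `category_scheme`.
#' @export
category_scheme <- function(categories, assignments) {
  categories <- trimws(as.character(categories))
  tm_assert(!anyDuplicated(categories), "category labels must be unique")
  if (!"Other" %in% categories) categories <- c(categories, "Other")
  tm_assert(categories[length(categories)] == "Other", "'Other' must be last")
  if (is.data.frame(assignments)) {
    tm_assert(all(c("theme", "category") %in% names(assignments)),
              "assignments need columns theme, category")
    assignments <- setNames(trimws(assignments$category), trimws(assignments$theme))
  }
  dup <- names(assignments)[duplicated(names(assignments))]
  tm_assert(length(dup) == 0, "theme(s) assigned more than once: ",
            paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(unname(assignments)), categories)
  tm_assert(length(bad) == 0, "assignment target(s) not in category list: ",
            paste(bad, collapse = ", "))
  structure(list(categories = categories, assignments = assignments),
            class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("<category_scheme> ", length(x$categories), " categories, ",
      length(x$assignments), " theme assignments\n", sep = "")
  invisible(x)
}

#' Read a category scheme from files
#'
#' @param scheme_path TSV with header `theme	category`, one assignment per
#'   line; `#` comments ignored.
#' @param categories_path Plain-text file, one category label per line in
#'   report order (`#` comments ignored). When `NULL` the category list is the
#'   set of assigned categories in order of first appearance, plus `"Other"`.
#' @return A `category_scheme`.
#' @export
read_category_scheme <- function(scheme_path, categories_path = NULL) {
  lines <- readLines(scheme_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))]
  df <- read.delim(text = paste(lines, collapse = "\n"), sep = "\t", quote = "",
                   stringsAsFactors = FALSE, colClasses = "character")
  cats <- if (!is.null(categories_path)) {
    cl <- readLines(categories_path, encoding = "UTF-8", warn = FALSE)
    trimws(cl[!grepl("^[[:space:]]*#", cl) & nzchar(trimws(cl))])
  } else {
    unique(df$category)
  }
  category_scheme(cats, df)
}

#' The packaged default category scheme
#'
#' The stakeholder priority categories (in their published order) plus the six
#' author-created categories, with the documented theme assignments from the
#' seed lexicon's themes. User-replaceable via [read_category_scheme()].
#'
#' @return A `category_scheme`.
#' @export
default_scheme <- function() {
  read_category_scheme(tm_file("category_scheme.tsv"), tm_file("categories.txt"))
}

#' Map canonical themes to their priority category
#'
#' @param theme Character vector of canonical theme labels.
#' @param scheme A `category_scheme`.
#' @return Character vector of category labels; themes without an assignment
#'   map to `"Other"`.
#' @examples
#' map_theme(c("schizophrenia", "recidivism", "church attendance"),
#'           default_scheme())
#' @export
map_theme <- function(theme, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  out <- unname(scheme$assignments[as.character(theme)])
  out[is.na(out)] <- "Other"
  out
}

#' Category sets per abstract
#'
#' An abstract belongs to a category iff at least one of its themes maps to
#' it; a category is never counted twice within one abstract (multi-label,
#' within-category dedup).
#'
#' @param corpus_themes A tibble with a `pmid` column and a `themes`
#'   list-column of canonical labels (as produced by [extract_corpus()]).
#' @param scheme A `category_scheme`.
#' @return The input tibble with an added `categories` list-column.
#' @export
categorize_corpus <- function(corpus_themes, scheme) {
  stopifnot(is.data.frame(corpus_themes), "themes" %in% names(corpus_themes))
  corpus_themes$categories <- lapply(corpus_themes$themes, function(th) {
    if (!length(th)) character() else unique(map_theme(th, scheme))
  })
  corpus_themes
}
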