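# Corpus I/O: MEDLINE flat-file and PubMed XML parsing into abstract records,
# the corpus filters (has-abstract, year-window exclusion), country extraction
# from the first author's affiliation and World Bank income-group lookup.

#' Parse a MEDLINE or PubMed XML corpus file
#'
#' The format is auto-detected: files whose first non-blank character is `<`
#' are parsed as PubMed XML (`<PubmedArticle>` elements via xml2), anything
#' else as MEDLINE flat format (`PMID-`/`TI  -`/`AB  -`/`DP  -`/`AD  -` tags
#' with 6-space continuation lines, records separated by blank lines). Only
#' the first author's affiliation (the first `AD`/`<Affiliation>`) is
#' retained. A record with no abstract gets `text = ""`; a record without a
#' parseable PMID is skipped with a warning.
#'
#' @param path Path to the corpus file.
#' @return A tibble with one row per citation: `pmid` (character), `year`
#'   (integer, `NA` when absent), `title`, `text` (abstract body, `""` when
#'   absent), `affiliation` (verbatim first-author affiliation, `""` when
#'   absent).
#' @export
parse_medline <- function(path) {
  tm_assert(file.exists(path), "no such corpus file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  first <- trimws(lines[nzchar(trimws(lines))][1])
  if (!is.na(first) && startsWith(first, "<")) {
    .parse_pubmed_xml(path)
  } else {
    .parse_medline_flat(lines)
  }
}

.record_tibble <- function(rows) {
  if (!length(rows)) {
    return(tibble(pmid = character(), year = integer(), title = character(),
                  text = character(), affiliation = character()))
  }
  as_tibble(do.call(rbind, rows))
}

.parse_medline_flat <- function(lines) {
  recs <- split(lines, cumsum(!nzchar(trimws(lines))))
  rows <- list()
  for (rec in recs) {
    rec <- rec[nzchar(trimws(rec))]
    if (!length(rec)) next
    tags <- list()
    cur <- NULL
    ok <- TRUE
    for (ln in rec) {
      if (grepl("^[A-Z0-9]{1,4}\\s*- ", ln)) {
        cur <- sub("^([A-Z0-9]{1,4})\\s*- .*$", "\\1", ln)
        val <- sub("^[A-Z0-9]{1,4}\\s*- ", "", ln)
        tags[[cur]] <- c(tags[[cur]], val)
      } else if (grepl("^\\s{6}", ln) && !is.null(cur)) {
        n <- length(tags[[cur]])
        tags[[cur]][n] <- paste(tags[[cur]][n], trimws(ln))
      } else {
        ok <- FALSE
        break
      }
    }
    if (!ok || is.null(tags$PMID)) {
      warning("skipping malformed MEDLINE record", call. = FALSE)
      next
    }
    year <- NA_integer_
    if (!is.null(tags$DP)) {
      y <- regmatches(tags$DP[1], regexpr("\\b(1[89]|20)\\d{2}\\b", tags$DP[1]))
      if (length(y)) year <- as.integer(y)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pmid = trimws(tags$PMID[1]),
      year = year,
      title = if (is.null(tags$TI)) "" else paste(tags$TI, collapse = " "),
      text = if (is.null(tags$AB)) "" else paste(tags$AB, collapse = " "),
      affiliation = if (is.null(tags$AD)) "" else tags$AD[1],
      stringsAsFactors = FALSE
    )
  }
  .record_tibble(rows)
}

.parse_pubmed_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparseable PubMed XML: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  rows <- lapply(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      warning("skipping PubmedArticle without PMID", call. = FALSE)
      return(NULL)
    }
    year_node <- xml2::xml_find_first(a, ".//Article/Journal/JournalIssue/PubDate/Year")
    year <- suppressWarnings(as.integer(xml2::xml_text(year_node)))
    if (is.na(year)) {
      md <- xml2::xml_text(xml2::xml_find_first(
        a, ".//Article/Journal/JournalIssue/PubDate/MedlineDate"))
      y <- regmatches(md, regexpr("\\b(1[89]|20)\\d{2}\\b", md))
      if (length(y)) year <- as.integer(y)
    }
    abst <- xml2::xml_find_all(a, ".//Article/Abstract/AbstractText")
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//Article/ArticleTitle"))
    aff <- xml2::xml_text(xml2::xml_find_first(
      a, ".//Article/AuthorList/Author[1]//AffiliationInfo/Affiliation"))
    data.frame(
      pmid = pmid, year = year,
      title = ifelse(is.na(title), "", title),
      text = paste(xml2::xml_text(abst), collapse = " "),
      affiliation = ifelse(is.na(aff), "", aff),
      stringsAsFactors = FALSE
    )
  })
  .record_tibble(Filter(Negate(is.null), rows))
}

#' Write records as a MEDLINE flat file
#'
#' Inverse of the flat-format branch of [parse_medline()]:
#' pmid/year/title/text round-trip exactly.
#'
#' @param records A record tibble (`pmid`, `year`, `title`, `text`,
#'   `affiliation`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_medline <- function(records, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0("PMID- ", records$pmid[i]), con)
    if (!is.na(records$year[i])) writeLines(paste0("DP  - ", records$year[i]), con)
    if (nzchar(records$title[i])) writeLines(paste0("TI  - ", records$title[i]), con)
    if (nzchar(records$text[i])) writeLines(paste0("AB  - ", records$text[i]), con)
    if (nzchar(records$affiliation[i])) writeLines(paste0("AD  - ", records$affiliation[i]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Apply the corpus filters
#'
#' Reproduces the corpus construction semantics: citations with no abstract
#' are removed first, then citations from excluded years (e.g. the partial
#' final year of a retrieval window). The three parts partition the input, so
#' counts are conserved.
#'
#' @param records A record tibble from [parse_medline()].
#' @param exclude_years Integer vector of years to drop (default none).
#' @return A list with tibbles `kept`, `dropped_no_abstract`, `dropped_year`
#'   and a named integer vector `tally` (`n_input`, `n_kept`,
#'   `n_no_abstract`, `n_year_excluded`).
#' @export
filter_corpus <- function(records, exclude_years = integer()) {
  stopifnot(is.data.frame(records))
  no_ab <- !nzchar(trimws(records$text))
  dropped_no_abstract <- records[no_ab, , drop = FALSE]
  rest <- records[!no_ab, , drop = FALSE]
  bad_year <- !is.na(rest$year) & rest$year %in% as.integer(exclude_years)
  list(
    kept = as_tibble(rest[!bad_year, , drop = FALSE]),
    dropped_no_abstract = as_tibble(dropped_no_abstract),
    dropped_year = as_tibble(rest[bad_year, , drop = FALSE]),
    tally = c(
      n_input = nrow(records),
      n_kept = sum(!bad_year),
      n_no_abstract = sum(no_ab),
      n_year_excluded = sum(bad_year)
    )
  )
}

# ---- country and income-group handling -------------------------------------

#' Read a country/income-group table
#'
#' @param path TSV with header `name	income_group	canonical`; one row per
#'   country name or alias. `income_group` is one of `high`, `upper-middle`,
#'   `lower-middle`, `low`; `canonical` is empty for primary names and holds
#'   the primary name for alias rows (e.g. `UK` -> `United Kingdom`).
#' @return An object of class `income_table`.
#' @export
read_income_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  fy <- regmatches(lines, regexpr("fiscal[ -]?year:\\s*\\S+", lines, ignore.case = TRUE))
  fy <- if (length(fy)) sub(".*:\\s*", "", fy[1]) else "unspecified"
  lines <- lines[!grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))]
  df <- read.delim(text = paste(lines, collapse = "\n"), sep = "\t", quote = "",
                   stringsAsFactors = FALSE, colClasses = "character")
  tm_assert(all(c("name", "income_group", "canonical") %in% names(df)),
            "income table needs columns name, income_group, canonical")
  df$canonical[is.na(df$canonical)] <- ""
  groups <- c("high", "upper-middle", "lower-middle", "low")
  bad <- setdiff(unique(df$income_group), groups)
  tm_assert(length(bad) == 0, "unknown income group(s): ", paste(bad, collapse = ", "))
  df$canonical <- ifelse(nzchar(df$canonical), df$canonical, df$name)
  structure(list(table = df, fiscal_year = fy, groups = groups),
            class = "income_table")
}

#' @export
print.income_table <- function(x, ...) {
  cat("<income_table> ", nrow(x$table), " names (fiscal year ",
      x$fiscal_year, ")\n", sep = "")
  invisible(x)
}

#' The packaged World Bank income classification
#'
#' Country names and common aliases with their four-way World Bank income
#' group (fiscal-year tagged; see the file header). User-replaceable via
#' [read_income_table()] to pin a different fiscal year.
#'
#' @return An `income_table`.
#' @export
default_income_table <- function() {
  read_income_table(tm_file("income_groups.tsv"))
}

#' Extract countries from an affiliation string
#'
#' Scans the comma/semicolon-separated segments of the first author's
#' affiliation from right to left (the country conventionally closes an
#' affiliation) and reports every recognized geoname, rightmost first,
#' resolved to its canonical country name. Email addresses and trailing
#' punctuation are ignored; matching is case-insensitive except for
#' short all-caps aliases (`UK`, `USA`).
#'
#' @param affiliation Character vector of affiliation strings.
#' @param table An `income_table` (supplies the known names and aliases).
#' @return A list (one element per affiliation) of character vectors of
#'   canonical country names; `character()` when none is recognized.
#' @examples
#' extract_countries(
#'   "School of Population Health, University of New South Wales, Sydney, Australia.",
#'   default_income_table()
#' )
#' @export
extract_countries <- function(affiliation, table = default_income_table()) {
  stopifnot(inherits(table, "income_table"))
  tab <- table$table
  short_caps <- nchar(tab$name) <= 3 & tab$name == toupper(tab$name)
  key <- ifelse(short_caps, tab$name, tolower(tab$name))
  lapply(as.character(affiliation), function(aff) {
    if (is.na(aff) || !nzchar(aff)) return(character())
    aff <- gsub("[[:space:]]*\\S+@\\S+", "", aff)              # strip emails
    aff <- sub("^.*?:", "", aff)                               # "Electronic address:" style
    segs <- strsplit(aff, "[,;]")[[1]]
    segs <- trimws(gsub("[.]+$", "", trimws(segs)))
    segs <- segs[nzchar(segs)]
    found <- character()
    for (seg in rev(segs)) {
      probe <- gsub("[[:space:]]+", " ", seg)
      hit <- match(probe, tab$name)
      if (is.na(hit)) hit <- match(ifelse(nchar(probe) <= 3 &
                                            probe == toupper(probe),
                                          probe, tolower(probe)), key)
      if (is.na(hit)) {
        # country as the final words of the segment ("Parkville VIC Australia");
        # a mixed-case capitalized word right before the tail means the tail is
        # part of a longer proper name ("New South Wales" is not Wales), while
        # lowercase words ("of") and all-caps state codes ("NSW") are fine
        words <- strsplit(probe, " ")[[1]]
        for (k in seq_along(words)) {
          prev <- if (k > 1) words[k - 1] else ""
          if (grepl("^[A-Z][a-z]", prev)) next
          tail_probe <- paste(words[k:length(words)], collapse = " ")
          hit <- match(ifelse(nchar(tail_probe) <= 3 &
                                tail_probe == toupper(tail_probe),
                              tail_probe, tolower(tail_probe)), key)
          if (!is.na(hit)) break
        }
      }
      if (!is.na(hit)) found <- c(found, tab$canonical[hit])
    }
    unique(found)
  })
}

#' Classify countries into a World Bank income group
#'
#' @param countries Character vector or list of character vectors of country
#'   names (as from [extract_countries()]). For a multi-country record the
#'   first listed country decides the group.
#' @param table An `income_table`.
#' @return Character vector with one of `"high"`, `"upper-middle"`,
#'   `"lower-middle"`, `"low"`, or `"unknown"` (empty list or unrecognized
#'   country, the latter with a warning).
#' @examples
#' classify_income(list("Australia", "Malawi", character()), default_income_table())
#' @export
classify_income <- function(countries, table = default_income_table()) {
  stopifnot(inherits(table, "income_table"))
  if (!is.list(countries)) countries <- as.list(countries)
  tab <- table$table
  vapply(countries, function(cc) {
    cc <- cc[!is.na(cc)]
    if (!length(cc)) return("unknown")
    hit <- match(tolower(cc[1]), tolower(tab$name))
    if (is.na(hit)) {
      warning("country not in income table: ", cc[1], call. = FALSE)
      return("unknown")
    }
    # resolve alias, then take the canonical row's group
    canon <- tab$canonical[hit]
    tab$income_group[match(canon, tab$canonical)]
  }, character(1))
}
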