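# The theme dictionary (gazetteer): loading, validation and longest-match
# scanning. Entries map surface terms (synonyms, acronyms, abbreviations) to
# canonical theme labels; scanning supplies the "semantic placeholder" matches
# that the anchor rules may then license as extracted themes.

#' Construct a theme lexicon
#'
#' A lexicon is a validated set of entries mapping a surface term to its
#' canonical theme label, with an optional priority-category label (an empty
#' category later resolves to `"Other"`). Matching behaviour per entry:
#'
#' * `exact = TRUE` entries match case-sensitively and without plural
#'   tolerance. By default an entry is exact when its surface is an all-caps
#'   token of at most 4 characters (`"HIV"`, `"HCV"`, `"TB"`), so acronyms do
#'   not collide with common words.
#' * all other entries match case-insensitively, and the final token tolerates
#'   a simple plural (`"s"`/`"es"`) in either direction.
#'
#' Every canonical label must itself be present as a surface (self-mapping
#' closure); by default missing self-entries are added automatically.
#'
#' @param surface Character vector of surface terms (1..8 tokens each).
#' @param canonical Canonical theme label per surface.
#' @param category Priority-category label per surface (`""` allowed).
#' @param exact Logical vector or `NA` (auto-detect acronyms as above).
#' @param complete_canonicals Add self-mapping entries for canonicals that do
#'   not appear as surfaces (default `TRUE`).
#' @return An object of class `theme_lexicon`.
#' @examples
#' lex <- lexicon(
#'   surface   = c("HIV", "AIDS", "human immunodeficiency virus"),
#'   canonical = c("HIV", "HIV", "HIV"),
#'   category  = "Infectious disease and infections"
#' )
#' nrow(lex$entries)
#' @export
lexicon <- function(surface, canonical, category = "", exact = NA,
                    complete_canonicals = TRUE) {
  surface <- trimws(gsub("[[:space:]]+", " ", as.character(surface)))
  canonical <- trimws(as.character(canonical))
  n <- length(surface)
  category <- rep_len(ifelse(is.na(category), "", trimws(as.character(category))), n)
  exact <- rep_len(as.logical(exact), n)

  tm_assert(n > 0, "lexicon is empty")
  tm_assert(all(nzchar(surface)), "lexicon: empty surface term")
  tm_assert(length(canonical) == n && all(nzchar(canonical)),
            "lexicon: every entry needs a non-empty canonical label")

  auto <- nchar(surface) <= 4 & surface == toupper(surface) &
    grepl("[A-Z]", surface) & !grepl("[[:space:]]", surface)
  exact[is.na(exact)] <- auto[is.na(exact)]

  if (complete_canonicals) {
    missing <- setdiff(unique(canonical), unique(c(surface, tolower(surface))))
    missing <- missing[!tolower(missing) %in% tolower(surface)]
    if (length(missing)) {
      cat_of <- vapply(missing, function(cn) {
        hit <- category[canonical == cn & nzchar(category)]
        if (length(hit)) hit[1] else ""
      }, character(1))
      surface <- c(surface, missing)
      canonical <- c(canonical, missing)
      category <- c(category, cat_of)
      aut2 <- nchar(missing) <= 4 & missing == toupper(missing) &
        grepl("[A-Z]", missing) & !grepl("[[:space:]]", missing)
      exact <- c(exact, aut2)
    }
  }

  entries <- data.frame(
    surface = surface, canonical = canonical, category = category,
    exact = exact, stringsAsFactors = FALSE
  )
  # fold key: exact entries keep case, others are lowercased
  entries$fold <- ifelse(entries$exact, entries$surface, tolower(entries$surface))
  entries <- entries[!duplicated(entries[c("fold", "canonical")]), , drop = FALSE]

  dup <- entries$fold[duplicated(entries$fold)]
  if (length(dup)) {
    stop("lexicon: surface term(s) mapped to more than one canonical label: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_cat <- tapply(entries$category[nzchar(entries$category)],
                    entries$canonical[nzchar(entries$category)],
                    function(x) length(unique(x)) > 1)
  if (any(unlist(bad_cat))) {
    stop("lexicon: canonical label(s) assigned to more than one category: ",
         paste(names(bad_cat)[unlist(bad_cat)], collapse = ", "), call. = FALSE)
  }
  missing_self <- setdiff(tolower(unique(entries$canonical)), tolower(entries$surface))
  tm_assert(length(missing_self) == 0,
            "lexicon: canonical label(s) lacking a self-mapping surface: ",
            paste(missing_self, collapse = ", "))

  toks <- lapply(entries$surface, function(s) tokenize(s)$token)
  ntok <- lengths(toks)
  tm_assert(all(ntok >= 1 & ntok <= 8), "lexicon: surfaces must span 1..8 tokens")

  rownames(entries) <- NULL
  structure(
    list(
      entries = entries,
      tokens = toks,
      ntok = ntok,
      index = .lex_index(entries, toks, ntok)
    ),
    class = "theme_lexicon"
  )
}

# first-token index: lowercase first token -> entry rows, longest first
.lex_index <- function(entries, toks, ntok) {
  first <- tolower(vapply(toks, `[`, character(1), 1L))
  ord <- order(-ntok, -nchar(entries$surface))
  idx <- split(ord, first[ord])
  list2env(idx, envir = new.env(parent = emptyenv()))
}

#' @export
print.theme_lexicon <- function(x, ...) {
  cat("<theme_lexicon> ", nrow(x$entries), " surface terms, ",
      length(unique(x$entries$canonical)), " canonical themes\n", sep = "")
  invisible(x)
}

#' Load a lexicon from a TSV file
#'
#' The file is UTF-8, tab-separated, with header columns `surface`,
#' `canonical`, `category` and optionally `exact` (logical); lines starting
#' with `#` are comments. Duplicate identical rows are collapsed silently;
#' the same surface mapped to two different canonical labels is a load error.
#'
#' @param path Path to the TSV file.
#' @param complete_canonicals See [lexicon()].
#' @return A `theme_lexicon`.
#' @seealso [default_lexicon()] for the packaged seed dictionary.
#' @export
load_lexicon <- function(path, complete_canonicals = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))]
  tm_assert(length(lines) >= 2, "lexicon file is empty: ", path)
  df <- read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                   quote = "", stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("surface", "canonical", "category")
  tm_assert(all(need %in% names(df)),
            "lexicon file must have columns surface, canonical, category: ", path)
  exact <- if ("exact" %in% names(df)) {
    ifelse(df$exact %in% c("TRUE", "true", "1"), TRUE,
           ifelse(df$exact %in% c("FALSE", "false", "0"), FALSE, NA))
  } else NA
  lexicon(df$surface, df$canonical, df$category, exact = exact,
          complete_canonicals = complete_canonicals)
}

#' Write a lexicon back to TSV
#'
#' Inverse of [load_lexicon()]: `load_lexicon(write_lexicon(lex, f))` yields an
#' identical entry set.
#'
#' @param lex A `theme_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "theme_lexicon"))
  df <- lex$entries[c("surface", "canonical", "category", "exact")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged seed lexicon
#'
#' A starter dictionary assembled from the themes, synonyms, acronyms and
#' category assignments that are explicitly documented for this extraction
#' task. The original working dictionary of roughly 2500 terms is not
#' published, so the seed is intentionally small and fully user-replaceable:
#' pass any [load_lexicon()] result wherever a lexicon is accepted.
#'
#' @return A `theme_lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(tm_file("seed_lexicon.tsv"))
}

# token equality under the entry's matching regime; plurals only on last token
.tok_eq <- function(txt, ent, exact, last) {
  if (exact) return(txt == ent)
  t <- tolower(txt); e <- tolower(ent)
  if (t == e) return(TRUE)
  if (!last) return(FALSE)
  t == paste0(e, "s") || t == paste0(e, "es") ||
    e == paste0(t, "s") || e == paste0(t, "es")
}

# candidate index keys for a text token (plural variants of single-token entries)
.probe_keys <- function(tok) {
  t <- tolower(tok)
  keys <- c(t, paste0(t, "s"), paste0(t, "es"))
  if (nchar(t) > 2 && endsWith(t, "es")) keys <- c(keys, substr(t, 1, nchar(t) - 2))
  if (nchar(t) > 1 && endsWith(t, "s")) keys <- c(keys, substr(t, 1, nchar(t) - 1))
  unique(keys)
}

#' Scan text with the lexicon (gazetteer lookup)
#'
#' Finds all dictionary term matches in `text` under leftmost-longest
#' resolution on token boundaries: at each position the longest matching entry
#' wins and scanning resumes after it, so no returned match is nested inside
#' another. Matching is case-insensitive with simple plural tolerance on the
#' final token, except for `exact` entries (acronyms), which match verbatim.
#'
#' @param text Character scalar (e.g. an abstract or one sentence).
#' @param lex A `theme_lexicon`.
#' @return A tibble with one row per match: `surface_text` (as it appears in
#'   the text), `start`, `end` (0-based half-open span), `surface`,
#'   `canonical`, `category` of the matched entry.
#' @examples
#' lex <- lexicon(c("criminality", "severe injury", "injury"),
#'                c("criminality", "severe injury", "injury"))
#' scan_terms("Criminality is a risk factor for severe injury.", lex)
#' @export
scan_terms <- function(text, lex) {
  stopifnot(inherits(lex, "theme_lexicon"))
  toks <- tokenize(text)
  n <- nrow(toks)
  hits <- vector("list", 0L)
  i <- 1L
  while (i <= n) {
    cand <- unlist(lapply(.probe_keys(toks$token[i]), function(k) {
      if (exists(k, envir = lex$index, inherits = FALSE)) get(k, envir = lex$index) else integer()
    }), use.names = FALSE)
    if (length(cand)) {
      cand <- cand[order(-lex$ntok[cand], -nchar(lex$entries$surface[cand]))]
      for (e in cand) {
        k <- lex$ntok[e]
        if (i + k - 1L > n) next
        ent_toks <- lex$tokens[[e]]
        ok <- TRUE
        for (j in seq_len(k)) {
          if (!.tok_eq(toks$token[i + j - 1L], ent_toks[j],
                       lex$entries$exact[e], last = (j == k))) {
            ok <- FALSE
            break
          }
          # inter-token gap may hold only whitespace or a slash (sentence
          # punctuation must not be skipped over by a multiword term)
          if (j > 1L && !grepl("^[[:space:]/]*$",
                               span_str(text, toks$end[i + j - 2L],
                                        toks$start[i + j - 1L]))) {
            ok <- FALSE
            break
          }
        }
        if (ok) {
          hits[[length(hits) + 1L]] <- data.frame(
            start = toks$start[i], end = toks$end[i + k - 1L],
            entry = e, stringsAsFactors = FALSE
          )
          i <- i + k - 1L
          break
        }
      }
    }
    i <- i + 1L
  }
  if (!length(hits)) {
    return(tibble(
      surface_text = character(), start = integer(), end = integer(),
      surface = character(), canonical = character(), category = character()
    ))
  }
  h <- do.call(rbind, hits)
  tibble(
    surface_text = span_str(text, h$start, h$end),
    start = h$start, end = h$end,
    surface = lex$entries$surface[h$entry],
    canonical = lex$entries$canonical[h$entry],
    category = lex$entries$category[h$entry]
  )
}

#' Canonical theme labels of a lexicon
#'
#' @param lex A `theme_lexicon`.
#' @return Character vector of unique canonical labels.
#' @export
canonical_themes <- function(lex) {
  unique(lex$entries$canonical)
}
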