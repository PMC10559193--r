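# The anchor-pattern rule engine. A rule couples a semi-frozen lexical
# expression (the anchor, a case-insensitive regex such as variants of
# "is a risk factor for") with slot descriptors saying where, relative to the
# anchor, dictionary matches are licensed for extraction. Rules are data, not
# code: the packaged default set covers the documented anchor families and is
# meant to be extended by users.

.slot_sides <- c("left", "right", "within")
.coord_tokens <- c("and", "or")

#' Construct a rule set
#'
#' @param rules A list of rules; each rule is a list with fields `id`
#'   (unique string), `anchor` (a Perl regex matched case-insensitively within
#'   one sentence) and `slots` (list of slots, each with `side` one of
#'   `"left"`, `"right"`, `"within"`, `max_token_gap` (non-negative integer;
#'   ignored for `"within"`) and `allow_coordination` (logical: `"and"`/`"or"`
#'   tokens and commas do not count toward the gap)).
#' @param version Free-text version tag for the set.
#' @return An object of class `theme_rules`.
#' @examples
#' rs <- rule_set(list(list(
#'   id = "rf", anchor = "is a risk factor for",
#'   slots = list(
#'     list(side = "left", max_token_gap = 4, allow_coordination = TRUE),
#'     list(side = "right", max_token_gap = 4, allow_coordination = TRUE)
#'   )
#' )))
#' @export
rule_set <- function(rules, version = "unversioned") {
  tm_assert(is.list(rules), "rules must be a list")
  seen <- character()
  out <- lapply(rules, function(r) {
    tm_assert(is.list(r), "each rule must be a list")
    extra <- setdiff(names(r), c("id", "anchor", "slots"))
    tm_assert(length(extra) == 0,
              "rule has unknown field(s): ", paste(extra, collapse = ", "),
              if (!is.null(r$id)) paste0(" (rule '", r$id, "')") else "")
    tm_assert(is.character(r$id) && length(r$id) == 1 && nzchar(r$id),
              "rule without an id")
    ok <- tryCatch({grepl(r$anchor, "probe", perl = TRUE, ignore.case = TRUE); TRUE},
                   error = function(e) FALSE, warning = function(e) FALSE)
    tm_assert(ok, "rule '", r$id, "': anchor regex does not compile: ", r$anchor)
    tm_assert(is.list(r$slots) && length(r$slots) >= 1,
              "rule '", r$id, "': at least one slot required")
    r$slots <- lapply(r$slots, function(s) {
      extra <- setdiff(names(s), c("side", "max_token_gap", "allow_coordination"))
      tm_assert(length(extra) == 0,
                "rule '", r$id, "': slot has unknown field(s): ",
                paste(extra, collapse = ", "))
      tm_assert(is.character(s$side) && s$side %in% .slot_sides,
                "rule '", r$id, "': slot side must be one of ",
                paste(.slot_sides, collapse = "/"))
      gap <- if (is.null(s$max_token_gap)) 6L else as.integer(s$max_token_gap)
      tm_assert(!is.na(gap) && gap >= 0L, "rule '", r$id, "': max_token_gap >= 0")
      coord <- if (is.null(s$allow_coordination)) TRUE else isTRUE(s$allow_coordination)
      list(side = s$side, max_token_gap = gap, allow_coordination = coord)
    })
    r[c("id", "anchor", "slots")]
  })
  ids <- vapply(out, `[[`, character(1), "id")
  dup <- ids[duplicated(ids)]
  tm_assert(length(dup) == 0, "duplicate rule id(s): ", paste(dup, collapse = ", "))
  structure(list(rules = out, version = as.character(version)),
            class = "theme_rules")
}

#' @export
print.theme_rules <- function(x, ...) {
  cat("<theme_rules> ", length(x$rules), " rules (version ", x$version, ")\n",
      sep = "")
  invisible(x)
}

#' Compile a rule file
#'
#' Reads a JSON rules document of the form
#' `{"version": "...", "rules": [{"id", "anchor", "slots": [...]}, ...]}`
#' and validates it (unknown fields are rejected; a malformed anchor is a
#' compile error naming the rule).
#'
#' @param path Path to a JSON rules file.
#' @return A `theme_rules` object.
#' @seealso [default_rules()], [write_rules()]
#' @export
compile_rules <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tm_assert(is.list(doc) && !is.null(doc$rules), "rules file must contain a 'rules' array: ", path)
  extra <- setdiff(names(doc), c("version", "rules"))
  tm_assert(length(extra) == 0, "rules file has unknown top-level field(s): ",
            paste(extra, collapse = ", "))
  rule_set(doc$rules, version = if (is.null(doc$version)) "unversioned" else doc$version)
}

#' Serialize a rule set to JSON
#'
#' Deterministic writer; `compile_rules(write_rules(rs, f))` round-trips the
#' set exactly, and writing the re-read set reproduces the file byte for byte.
#'
#' @param rules A `theme_rules` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "theme_rules"))
  doc <- list(version = rules$version, rules = rules$rules)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' The packaged default rule set
#'
#' Anchor families covered: risk/protective factor, predictor, association
#' ("associated with", "related to", "correlated with"), prevalence and
#' outcome rates, deaths/mortality from, causal frames ("effect of X on Y"),
#' history/diagnosis of, and screening. The original 61 working rules are not
#' published; this set re-creates the documented families and is
#' user-extensible via [compile_rules()].
#'
#' @return A `theme_rules` object.
#' @export
default_rules <- function() {
  compile_rules(tm_file("default_rules.json"))
}

#' Tabulate the anchors of a rule set
#'
#' Documentation aid: one row per rule with its anchor pattern and slot
#' layout.
#'
#' @param rules A `theme_rules` object.
#' @return A tibble with columns `rule_id`, `anchor`, `slots` (compact
#'   rendering like `"left<=6+coord, right<=6+coord"`).
#' @export
list_anchor_inventory <- function(rules) {
  stopifnot(inherits(rules, "theme_rules"))
  if (!length(rules$rules)) {
    return(tibble(rule_id = character(), anchor = character(), slots = character()))
  }
  tibble(
    rule_id = vapply(rules$rules, `[[`, character(1), "id"),
    anchor = vapply(rules$rules, `[[`, character(1), "anchor"),
    slots = vapply(rules$rules, function(r) {
      paste(vapply(r$slots, function(s) {
        if (s$side == "within") "within"
        else paste0(s$side, "<=", s$max_token_gap,
                    if (s$allow_coordination) "+coord" else "")
      }, character(1)), collapse = ", ")
    }, character(1))
  )
}

# token gap between a term match and the anchor on one side; coordination
# tokens are not counted when the slot allows coordination
.slot_gap <- function(toks, lo, hi, coord) {
  if (hi <= lo) return(0L)
  sel <- toks$start >= lo & toks$end <= hi
  if (coord) sel <- sel & !(tolower(toks$token) %in% .coord_tokens)
  sum(sel)
}

#' Extract theme mentions from one abstract
#'
#' The core extraction step: the text is split into sentences
#' ([split_sentences()]); within each sentence every dictionary match
#' ([scan_terms()]) is kept only if some rule licenses it — i.e. the rule's
#' anchor matches the sentence and the term sits in one of the rule's slots
#' (within `max_token_gap` tokens of the anchor on the slot's side, with
#' `"and"`/`"or"` and commas not counting toward the gap when coordination is
#' allowed, or inside the anchor span for `"within"` slots). A dictionary
#' match licensed by no rule is not extracted. The same term licensed by
#' several rules yields one mention per licensing rule (duplicates are later
#' removed by [unify_mentions()]).
#'
#' @param text Abstract text (character scalar).
#' @param rules A `theme_rules` object.
#' @param lex A `theme_lexicon`.
#' @return A tibble with one row per mention: `canonical`, `surface_text`,
#'   `start`, `end` (0-based half-open span in `text`), `rule_id`,
#'   `sentence_index`. Deterministically ordered by sentence, rule order,
#'   anchor position and term position.
#' @examples
#' lex <- lexicon(c("criminality", "severe injury"), c("criminality", "severe injury"))
#' extract_mentions("Criminality is a risk factor for severe injury.",
#'                  default_rules(), lex)
#' @export
extract_mentions <- function(text, rules, lex) {
  stopifnot(inherits(rules, "theme_rules"), inherits(lex, "theme_lexicon"))
  empty <- tibble(canonical = character(), surface_text = character(),
                  start = integer(), end = integer(), rule_id = character(),
                  sentence_index = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  sents <- split_sentences(text)
  rows <- list()
  for (si in seq_len(nrow(sents))) {
    stext <- sents$text[si]
    terms <- scan_terms(stext, lex)
    if (!nrow(terms)) next
    toks <- tokenize(stext)
    for (r in rules$rules) {
      am <- gregexpr(r$anchor, stext, perl = TRUE, ignore.case = TRUE)[[1]]
      if (am[1] == -1L) next
      a_start <- as.integer(am) - 1L
      a_end <- a_start + attr(am, "match.length")
      for (ai in seq_along(a_start)) {
        for (s in r$slots) {
          lic <- switch(
            s$side,
            within = which(terms$start >= a_start[ai] & terms$end <= a_end[ai]),
            right = which(terms$start >= a_end[ai] &
                          vapply(seq_len(nrow(terms)), function(ti) {
                            terms$start[ti] >= a_end[ai] &&
                              .slot_gap(toks, a_end[ai], terms$start[ti],
                                        s$allow_coordination) <= s$max_token_gap
                          }, logical(1))),
            left = which(terms$end <= a_start[ai] &
                         vapply(seq_len(nrow(terms)), function(ti) {
                           terms$end[ti] <= a_start[ai] &&
                             .slot_gap(toks, terms$end[ti], a_start[ai],
                                       s$allow_coordination) <= s$max_token_gap
                         }, logical(1)))
          )
          for (ti in lic) {
            rows[[length(rows) + 1L]] <- data.frame(
              canonical = terms$canonical[ti],
              surface_text = terms$surface_text[ti],
              start = terms$start[ti] + sents$start[si],
              end = terms$end[ti] + sents$start[si],
              rule_id = r$id,
              sentence_index = si,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  as_tibble(do.call(rbind, rows))
}
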