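# Shared fixtures and independent oracles. Fixture lexicons and rule sets are
# built in code so tests never depend on the packaged seed data unless they
# are explicitly about it.

tiny_lexicon <- function() {
  lexicon(
    surface = c("criminality", "severe injury", "injury", "hepatitis C",
                "HPC", "hepatitis", "HIV", "AIDS", "recidivism",
                "substance use", "alcohol use", "prisons"),
    canonical = c("criminality", "severe injury", "injury", "hepatitis C",
                  "hepatitis C", "hepatitis", "HIV", "HIV", "recidivism",
                  "substance use", "alcohol use", "prisons"),
    category = ""
  )
}

tiny_rules <- function() {
  rule_set(list(
    list(id = "rf",
         anchor = "\\b(?:is|was|are|were)\\s+a\\s+risk\\s+factor\\s+for\\b",
         slots = list(
           list(side = "left", max_token_gap = 6, allow_coordination = TRUE),
           list(side = "right", max_token_gap = 6, allow_coordination = TRUE)
         )),
    list(id = "pred",
         anchor = "\\bpredictors?\\s+of\\b",
         slots = list(
           list(side = "right", max_token_gap = 6, allow_coordination = TRUE)
         )),
    list(id = "prev",
         anchor = "\\bprevalence\\s+of\\b",
         slots = list(
           list(side = "right", max_token_gap = 4, allow_coordination = TRUE)
         ))
  ), version = "tiny")
}

# ---- brute-force gazetteer oracle ------------------------------------------
# Enumerates every token window, tests it against every entry with its own
# (re-implemented) equality logic, then resolves overlaps greedily from the
# left taking the longest candidate at each leftmost start.

oracle_tok_eq <- function(txt, ent, exact, last) {
  if (exact) return(txt == ent)
  a <- tolower(txt); b <- tolower(ent)
  if (a == b) return(TRUE)
  if (!last) return(FALSE)
  strip <- function(z) {
    out <- c(z)
    if (grepl("es$", z) && nchar(z) > 2) out <- c(out, sub("es$", "", z))
    if (grepl("s$", z) && nchar(z) > 1) out <- c(out, sub("s$", "", z))
    out
  }
  length(intersect(strip(a), strip(b))) > 0
}

oracle_scan <- function(text, lex) {
  toks <- thememiner:::tokenize(text)
  n <- nrow(toks)
  ent <- lex$entries
  cands <- list()
  for (i in seq_len(n)) {
    for (e in seq_len(nrow(ent))) {
      k <- lex$ntok[e]
      if (i + k - 1 > n) next
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!oracle_tok_eq(toks$token[i + j - 1], lex$tokens[[e]][j],
                           ent$exact[e], j == k)) { ok <- FALSE; break }
        if (j > 1) {
          gap <- substring(text, toks$end[i + j - 2] + 1, toks$start[i + j - 1])
          if (!grepl("^[[:space:]/]*$", gap)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        cands[[length(cands) + 1]] <- data.frame(
          start = toks$start[i], end = toks$end[i + k - 1],
          ntok = k, canonical = ent$canonical[e]
        )
      }
    }
  }
  if (!length(cands)) {
    return(data.frame(start = integer(), end = integer(),
                      canonical = character()))
  }
  cand <- do.call(rbind, cands)
  cand <- cand[order(cand$start, -cand$ntok, -(cand$end - cand$start)), ]
  # rows are sorted by start, then longest first: the first row whose start
  # clears the previous selection is the leftmost-longest next match
  sel <- list()
  pos <- -1
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= pos) {
      sel[[length(sel) + 1]] <- cand[i, ]
      pos <- cand$end[i]
    }
  }
  out <- do.call(rbind, sel)
  out[c("start", "end", "canonical")]
}

# random text over a vocabulary mixing dictionary surfaces and distractors
random_text <- function(vocab, max_tokens = 50) {
  n <- sample.int(max_tokens, 1)
  words <- sample(vocab, n, replace = TRUE)
  paste(words, collapse = " ")
}

# ---- brute-force evaluation oracle -----------------------------------------

oracle_score <- function(pred, gold) {
  u <- union(unique(pred), unique(gold))
  tp <- fp <- fn <- 0L
  for (t in u) {
    inp <- t %in% pred; ing <- t %in% gold
    if (inp && ing) tp <- tp + 1L
    if (inp && !ing) fp <- fp + 1L
    if (!inp && ing) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

# all subsets of a set, as a list of character vectors
all_subsets <- function(x) {
  out <- list(character())
  for (el in x) out <- c(out, lapply(out, c, el))
  out
}
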