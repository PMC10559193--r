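# Synthetic MEDLINE corpora with planted themes and gold annotations. The
# generator assembles each abstract from template sentences that render
# planted themes through rule-compatible anchor phrases, plus distractor
# sentences (a dictionary term with no licensing anchor: a false-positive
# probe) and filler sentences free of dictionary terms. Noise channels mirror
# the documented error classes: unknown-term plants (concepts outside the
# dictionary, the false-negative driver) and synonym rendering (standardization
# stressor). Everything is deterministic given the seed.

.anchor_templates_2 <- c(
  "%s is a risk factor for %s.",
  "%s was associated with %s.",
  "%s was predictive of %s.",
  "The effect of %s on %s was examined."
)
.anchor_templates_1 <- c(
  "The prevalence of %s was high in this cohort.",
  "%s was a significant risk factor.",
  "Predictors of %s were examined."
)
.anchor_template_3 <- "Predictors of %s included %s and %s."
.distractor_templates <- c(
  "The report also discusses %s in passing.",
  "Several programs concerning %s operate in this setting."
)
.filler_sentences <- c(
  "The cohort was followed over several years.",
  "Data were drawn from administrative sources.",
  "Further replication in other settings is needed.",
  "Recruitment and consent procedures are described."
)
.unknown_terms <- c(
  "problem gambling behaviour", "staff perceptions", "autonomic arousal",
  "dental caries experience", "auditory processing skills",
  "adjustment to custodial routines"
)

#' Configure the synthetic-corpus generator
#'
#' Defaults emulate the observed composition of the real retrieval: roughly
#' half the abstracts carry no extractable theme, about two themes per themed
#' abstract, a fifth of plants rendered through a non-canonical synonym, and a
#' country pool whose income-group mix matches the published output shares
#' (~85% high income, ~6% upper-middle, ~4% lower-middle, ~1% low, ~4%
#' without an affiliated country).
#'
#' @param seed Integer RNG seed; same config + seed gives byte-identical
#'   output files.
#' @param n_abstracts Number of citations to generate (>= 0).
#' @param themes_per_abstract Either a fixed integer `k`, or a list
#'   `list(kind = "poisson", lambda =)`; draws are clamped to `[1, 5]`.
#' @param synonym_rate Probability a planted theme is rendered via a
#'   non-canonical surface (synonym/acronym) when one exists.
#' @param no_theme_rate Probability an abstract carries no extractable theme.
#' @param unknown_term_rate Probability a planted concept is rendered with a
#'   term absent from the lexicon (goes to the FN ledger, not the gold file).
#' @param distractor_rate Probability of adding an anchor-less sentence
#'   containing a dictionary term that is not planted (FP probe: a correct
#'   extractor must not return it).
#' @param year_range Length-2 integer vector of publication years.
#' @param country_pool Named numeric vector of sampling weights; names are
#'   country names, `""` meaning no affiliated country. `NULL` for the
#'   default mix above.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_abstracts = 100L,
                             themes_per_abstract = list(kind = "poisson", lambda = 2),
                             synonym_rate = 0.2, no_theme_rate = 0.47,
                             unknown_term_rate = 0, distractor_rate = 0.15,
                             year_range = c(1990L, 2020L),
                             country_pool = NULL) {
  probs <- c(synonym = synonym_rate, no_theme = no_theme_rate,
             unknown = unknown_term_rate, distractor = distractor_rate)
  tm_assert(all(probs >= 0 & probs <= 1), "all rates must lie in [0, 1]")
  tm_assert(is.numeric(n_abstracts) && length(n_abstracts) == 1 && n_abstracts >= 0,
            "n_abstracts must be a single non-negative number")
  tm_assert(length(year_range) == 2 && year_range[1] <= year_range[2],
            "year_range must be c(from, to)")
  if (is.numeric(themes_per_abstract)) {
    themes_per_abstract <- list(kind = "fixed", k = as.integer(themes_per_abstract))
    tm_assert(themes_per_abstract$k >= 1, "fixed themes_per_abstract must be >= 1")
  } else {
    tm_assert(is.list(themes_per_abstract) &&
                themes_per_abstract$kind %in% c("fixed", "poisson"),
              "themes_per_abstract must be an integer or list(kind=, ...)")
  }
  if (is.null(country_pool)) {
    country_pool <- setNames(
      c(0.40, 0.18, 0.17, 0.06, 0.043,
        0.03, 0.02, 0.013,
        0.02, 0.01, 0.007,
        0.004, 0.004, 0.041),
      c("United States", "United Kingdom", "Australia", "Canada", "Sweden",
        "Brazil", "China", "South Africa",
        "India", "Nigeria", "Kenya",
        "Malawi", "Ethiopia", "") # "" = no affiliated country
    )
  }
  tm_assert(!is.null(names(country_pool)) && all(country_pool >= 0),
            "country_pool must be a named non-negative weight vector")
  structure(
    list(seed = as.integer(seed), n_abstracts = as.integer(n_abstracts),
         themes_per_abstract = themes_per_abstract,
         synonym_rate = synonym_rate, no_theme_rate = no_theme_rate,
         unknown_term_rate = unknown_term_rate,
         distractor_rate = distractor_rate,
         year_range = as.integer(year_range),
         country_pool = country_pool / sum(country_pool)),
    class = "generator_config"
  )
}

.cap_first <- function(x) {
  sub("^([a-z])", "\\U\\1", x, perl = TRUE)
}

# pick a rendering surface for a canonical theme
.render_surface <- function(canonical, lex, synonym_rate) {
  alts <- lex$entries$surface[lex$entries$canonical == canonical &
                                tolower(lex$entries$surface) != tolower(canonical)]
  if (length(alts) && runif(1) < synonym_rate) sample(alts, 1) else canonical
}

# templates whose scaffold (slots removed) must stay inert: no dictionary
# match and, for anchor templates, extraction of a probe instantiation must
# return exactly the probes
.check_templates <- function(lex) {
  scaffolds <- c(
    gsub("%s", "zzzq", c(.anchor_templates_2, .anchor_templates_1,
                         .anchor_template_3)),
    gsub("%s", "zzzq", .distractor_templates),
    .filler_sentences,
    .unknown_terms
  )
  bad <- scaffolds[vapply(scaffolds, function(s) nrow(scan_terms(s, lex)) > 0,
                          logical(1))]
  tm_assert(length(bad) == 0,
            "lexicon collides with generator template text: ",
            paste(bad, collapse = " | "))
}

# retain only anchor templates the rule set actually licenses (checked once
# per call with probe terms), so user-supplied rule files still yield F1 = 1
.usable_templates <- function(lex, rules) {
  cano <- canonical_themes(lex)
  probes <- head(cano, 2)
  if (length(probes) < 2) probes <- rep(probes, 2)
  lic_n <- function(tmpl, k) {
    sent <- do.call(sprintf, c(list(tmpl), as.list(rep(probes, length.out = k))))
    got <- unique(extract_mentions(.cap_first(sent), rules, lex)$canonical)
    setequal(got, unique(rep(probes, length.out = k)))
  }
  list(
    t2 = .anchor_templates_2[vapply(.anchor_templates_2, lic_n, logical(1), k = 2)],
    t1 = .anchor_templates_1[vapply(.anchor_templates_1, lic_n, logical(1), k = 1)],
    t3 = if (lic_n(.anchor_template_3, 3)) .anchor_template_3 else character()
  )
}

#' Generate a synthetic corpus with gold annotations
#'
#' Writes a MEDLINE flat file, a gold TSV (`pmid	theme`: the planted
#' canonical themes that are extractable, i.e. rendered through dictionary
#' terms) and a sidecar FN-ledger TSV (same columns: planted concepts
#' rendered through unknown terms, which a perfect extractor must miss).
#' Recall measured against gold plus ledger is therefore ~ `1 -
#' unknown_term_rate` by construction, while gold alone supports the
#' noise-free F1 = 1 contract.
#'
#' @param config A [generator_config()].
#' @param lex A `theme_lexicon`; generation fails early if the lexicon
#'   collides with the template scaffolds.
#' @param rules A `theme_rules` set; only anchor templates this set licenses
#'   are used.
#' @param dir Output directory.
#' @param basename Stem for the three output files.
#' @return A list with tibbles `records`, `gold`, `fn_ledger` and paths
#'   `medline`, `gold_path`, `fn_ledger_path`.
#' @export
generate_corpus <- function(config, lex = default_lexicon(),
                            rules = default_rules(),
                            dir = tempdir(), basename = "sim") {
  stopifnot(inherits(config, "generator_config"), inherits(lex, "theme_lexicon"))
  tm_assert(nrow(lex$entries) > 0, "lexicon is empty")
  .check_templates(lex)
  tmpl <- .usable_templates(lex, rules)
  tm_assert(length(tmpl$t1) > 0 && length(tmpl$t2) > 0,
            "rule set licenses none of the generator's anchor templates")
  cano <- canonical_themes(lex)
  set.seed(config$seed)

  rec_rows <- vector("list", config$n_abstracts)
  gold_rows <- list()
  fn_rows <- list()
  for (i in seq_len(config$n_abstracts)) {
    pmid <- as.character(900000L + i)
    year <- sample(seq.int(config$year_range[1], config$year_range[2]), 1)
    country <- sample(names(config$country_pool), 1, prob = config$country_pool)

    planted <- character()
    if (runif(1) >= config$no_theme_rate) {
      k <- if (config$themes_per_abstract$kind == "fixed") {
        config$themes_per_abstract$k
      } else {
        rpois(1, config$themes_per_abstract$lambda)
      }
      k <- min(max(k, 1L), 5L, length(cano) - 1L)
      planted <- sample(cano, k)
    }

    surfaces <- character(length(planted))
    known <- logical(length(planted))
    for (j in seq_along(planted)) {
      if (runif(1) < config$unknown_term_rate) {
        surfaces[j] <- sample(.unknown_terms, 1)
        known[j] <- FALSE
        fn_rows[[length(fn_rows) + 1L]] <-
          data.frame(pmid = pmid, theme = planted[j], stringsAsFactors = FALSE)
      } else {
        surfaces[j] <- .render_surface(planted[j], lex, config$synonym_rate)
        known[j] <- TRUE
        gold_rows[[length(gold_rows) + 1L]] <-
          data.frame(pmid = pmid, theme = planted[j], stringsAsFactors = FALSE)
      }
    }

    sents <- character()
    rem <- surfaces
    while (length(rem)) {
      ntok2 <- vapply(head(rem, 2), function(s) nrow(tokenize(s)), integer(1))
      if (length(rem) >= 3 && length(tmpl$t3) && all(ntok2 <= 2) &&
            runif(1) < 0.35) {
        sents <- c(sents, sprintf(tmpl$t3, rem[1], rem[2], rem[3]))
        rem <- rem[-(1:3)]
      } else if (length(rem) >= 2 && runif(1) < 0.7) {
        sents <- c(sents, sprintf(sample(tmpl$t2, 1), rem[1], rem[2]))
        rem <- rem[-(1:2)]
      } else {
        sents <- c(sents, sprintf(sample(tmpl$t1, 1), rem[1]))
        rem <- rem[-1]
      }
    }
    avail <- setdiff(cano, planted)
    if (length(avail) && runif(1) < config$distractor_rate) {
      sents <- c(sents,
                 sprintf(sample(.distractor_templates, 1), sample(avail, 1)))
    }
    sents <- c(sents, sample(.filler_sentences, sample(1:2, 1)))
    text <- paste(.cap_first(sample(sents)), collapse = " ")

    rec_rows[[i]] <- data.frame(
      pmid = pmid, year = year,
      title = sprintf("Synthetic epidemiological criminology abstract %d.", i),
      text = text,
      affiliation = if (nzchar(country)) {
        sprintf("School of Health Research, Example University, %s.", country)
      } else "",
      stringsAsFactors = FALSE
    )
  }

  records <- .record_tibble(rec_rows)
  gold_df <- if (length(gold_rows)) do.call(rbind, gold_rows) else
    data.frame(pmid = character(), theme = character())
  fn_df <- if (length(fn_rows)) do.call(rbind, fn_rows) else
    data.frame(pmid = character(), theme = character())

  medline <- file.path(dir, paste0(basename, ".medline"))
  gold_path <- file.path(dir, paste0(basename, "_gold.tsv"))
  fn_path <- file.path(dir, paste0(basename, "_fn_ledger.tsv"))
  write_medline(records, medline)
  # every generated pmid appears in the gold file (empty theme = no themes),
  # so evaluation covers no-theme abstracts too
  all_gold <- tibble(
    pmid = records$pmid,
    themes = lapply(records$pmid, function(p) unique(gold_df$theme[gold_df$pmid == p]))
  )
  write_gold(all_gold, gold_path)
  write.table(fn_df, fn_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")

  list(records = records, gold = all_gold, fn_ledger = as_tibble(fn_df),
       medline = medline, gold_path = gold_path, fn_ledger_path = fn_path)
}

#' The fixed worked-example corpus
#'
#' Six hand-written citations exercising every documented worked case: the
#' "criminality is a risk factor for severe injury" pattern sentence; an
#' abstract mentioning hepatitis C twice ("HPC" and "hepatitis C") that must
#' unify to one theme; the alcohol false-positive probe sentence (a
#' dictionary term with no licensing anchor, which must not be extracted); a
#' citation without an abstract; a 2021-dated citation (dropped when
#' `exclude_years = 2021`); and an abstract whose themes map only to the
#' "Other" category.
#'
#' @param dir Output directory for the MEDLINE and gold files.
#' @return As [generate_corpus()]: list with `records`, `gold`, `medline`,
#'   `gold_path`. The gold file covers every abstract-bearing record.
#' @export
worked_example_corpus <- function(dir = tempdir()) {
  records <- tibble(
    pmid = as.character(100001:100006),
    year = c(2005L, 2010L, 1998L, 2015L, 2021L, 2012L),
    title = c(
      "Offending histories and later harm (synthetic worked example).",
      "Blood-borne virus screening in custody (synthetic worked example).",
      "Sanction severity and self-report surveys (synthetic worked example).",
      "A citation without an abstract (synthetic worked example).",
      "An excluded partial-year citation (synthetic worked example).",
      "Workplace attitudes in secure settings (synthetic worked example)."
    ),
    text = c(
      "Criminality is a risk factor for severe injury. The cohort was followed after release.",
      "The prevalence of HPC was high among participants. Hepatitis C was associated with prior imprisonment.",
      "Violent offenders in State prisons are increasingly likely to report having used alcohol before committing their offenses, possibly illustrating the effect of more severe sanctions for alcohol-involved offenses.",
      "",
      "The prevalence of COVID-19 was high in this facility.",
      "Job satisfaction was associated with church attendance."
    ),
    affiliation = c(
      "School of Population Health, University of New South Wales, Sydney, Australia.",
      "Department of Public Health, Example University, Baltimore, United States.",
      "Bureau of Justice Research, Washington, USA.",
      "Institute of Population Health, University of Liverpool, Liverpool, United Kingdom.",
      "School of Psychology, University of New South Wales, Sydney, Australia.",
      ""
    )
  )
  gold <- tibble(
    pmid = records$pmid[records$pmid != "100004"],
    themes = list(
      c("criminality", "severe injury"),
      "hepatitis C",
      "sanctions", # studied determinant our rule set cannot license: a planted FN
      "COVID-19",
      c("job satisfaction", "church attendance")
    )
  )
  medline <- file.path(dir, "worked_example.medline")
  gold_path <- file.path(dir, "worked_example_gold.tsv")
  write_medline(records, medline)
  write_gold(gold, gold_path)
  list(records = records, gold = gold, medline = medline, gold_path = gold_path)
}
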