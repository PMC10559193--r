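---
title: "Rule-based theme mining for epidemiological criminology abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based theme mining for epidemiological criminology abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thememiner)
```

## The method

Epidemiological criminology — the study of health in offending and
incarcerated populations — reports its study determinants and outcomes
("themes": HIV, recidivism, substance use, ...) in abstracts written in a
fairly regular register. thememiner extracts those themes with a rule-based
method built from two components:

1. a **dictionary (gazetteer)** of surface terms mapped to canonical theme
   labels, which supplies candidate *semantic placeholders*; and
2. **anchor rules**: semi-frozen lexical expressions ("is a risk factor
   for", "predictors of", "was associated with", ...) encoded as regular
   expressions, each with *slots* describing where, relative to the anchor,
   a dictionary match is licensed for extraction.

In `"Criminality is a risk factor for severe injury."` the anchor matches
the copular frame and licenses the dictionary matches on either side, so the
sentence yields the themes *criminality* and *severe injury*. A dictionary
match in a sentence with no matching anchor is **not** extracted — this is
what keeps precision high, and the package's false-positive probes test it
directly.

Extracted mentions are standardized (synonyms and acronyms collapse to one
canonical label: "AIDS" → "HIV") and unified per abstract (duplicates
removed), giving one theme *set* per citation. Theme sets are then mapped to
stakeholder research-priority categories, stratified by the World Bank
income group of the first author's country, and aggregated into frequency
tables, annual trend series, and a priority-vs-output gap report.

```{r example}
lex <- default_lexicon()
rules <- default_rules()
extract_mentions("Criminality is a risk factor for severe injury.", rules, lex)
```

## Dictionary matching conventions

Several choices here are genuinely open — the register of biomedical
abstracts does not dictate them — so they are stated explicitly:

* **Tokens** are maximal alphanumeric runs; a hyphen joining two runs is
  word-internal. So `"post-traumatic"` is one token, and the term
  `"alcohol"` does not match inside `"alcohol-involved"`.
* **Case folding** is full lowercase, *except* entries of at most four
  characters written in all caps in the lexicon (`HIV`, `HCV`, `TB`, ...),
  which match case-sensitively and without plural tolerance. This prevents
  acronyms from colliding with common words ("AIDS" vs "hearing aids").
* **Plural tolerance**: the final token of a non-exact entry matches a
  simple `s`/`es` plural in either direction ("substance uses" ↔
  "substance use"). No further stemming or lemmatization is attempted.
* **Overlap resolution** is leftmost-longest: at each position the longest
  matching entry wins and scanning resumes after it, so no returned match is
  nested in another ("severe injury" suppresses the embedded "injury").
  This mirrors classical gazetteer behaviour and is deterministic.
* A multiword term never skips sentence punctuation between its tokens
  ("hepatitis. C" is not "hepatitis C"), which also makes scanning
  compositional across sentence-joined texts.

The packaged seed lexicon covers the themes, synonyms and category
assignments that are explicitly documented for this task; the full working
dictionary behind the published corpus figures (roughly 2500 terms) was
never released. Consequently the seed is deliberately small, validated, and
fully user-replaceable (`load_lexicon()`), and all unit tests run against
fixture lexicons built in code.

## Sentence segmentation and rule scope

Extraction is sentence-focused: anchors never license a term across a
sentence boundary. Splitting occurs at `.`, `!`, `?` followed by whitespace
and a capital or digit, with an abbreviation guard ("e.g.", "vs.", "Dr.",
single-letter initials); decimals never split because no whitespace follows
the period.

Each rule's slots have:

* `side`: `left` or `right` of the anchor, or `within` the anchor span;
* `max_token_gap` (default 6): the maximum number of tokens between anchor
  and term. Six tokens captures constructions like "X and Y were
  significant risk factors" without granting whole-sentence scope, which is
  the documented over-extraction failure mode of sentence-level rules;
* `allow_coordination` (default `TRUE`): `and`/`or` tokens and commas do
  not count toward the gap, so coordinated lists ("predictors of X included
  Y and Z") are captured.

The `within` side exists for frames whose two arguments bracket part of the
anchor, notably "effect of X on Y". Treating `effect of ... on` as a single
anchor with a `within` slot means the frame only licenses anything when it
is complete: "the effect of more severe sanctions for alcohol-involved
offenses" (no "on") licenses nothing, which is exactly the behaviour the
false-positive probe sentence demands.

The shipped rule file (16 rules) covers the documented anchor families:
risk/protective factor, predictor, association, correlation, prevalence and
rates, deaths/mortality from, causal effect/impact frames, history/diagnosis
of, and screening. The original working system used 61 rules that were not
published; rules here are data (`compile_rules()` on a JSON document), so
users can grow the set toward their corpus. Anchor matching is
case-insensitive, and anchors are bounded with `\b` so that alternations
like `is|was` cannot match inside words.

## Standardization, categories, income groups

Standardization is table-driven through the lexicon's `canonical` column —
the manual synonym mapping of the original workflow becomes a data artifact
with a single source of truth. Unification removes duplicate standardized
themes per abstract; `mention_count` retains the raw tally.

The category scheme lists the stakeholder-identified priority categories in
their published order, then six author-created catch-alls ("Justice
system", "Biomedical related", "Offense related", "Juveniles", "Behavior")
and the fallback "Other". Categories with no mapped theme (Hygiene,
Disability, Postrelease health maintenance, ...) are retained: representing
zero-output priorities is what makes the gap report meaningful. Two
documented inconsistencies were resolved in favour of the data tables: age,
sex and gender sit in "Biomedical related", and learning disability in
"Cognitive and intellectual disability".

Country attribution uses the first author's affiliation only: the country is
the rightmost recognized geoname (with alias handling for "UK", "USA",
compass-prefixed proper names such as "New South Wales" guarded against);
when several countries are recognized, the first element of the resulting
list decides the income group. The packaged income table is the World Bank
four-way classification, fiscal-year tagged (FY2022) and user-replaceable,
since the fiscal year used by the original study is unstated. Records with
no recognizable country are reported as their own "unknown" stratum and
excluded from the four group denominators.

## Evaluation semantics

Scoring is at the level of (abstract, standardized theme) pairs: detecting
any mention of a gold theme in an abstract is one true positive, so partial
mention detection is credited by unification, not by the scorer. Precision,
recall and F1 follow their standard definitions. Two under-determined
choices are made explicit and isolated:

* **Averaging** is micro by default (sum tp/fp/fn over abstracts, then form
  ratios), the corpus-level convention in information extraction; macro
  averaging is available behind a flag.
* **Absolute agreement** between two annotators is, per abstract, the
  fraction of the union of marked themes that both marked, micro-averaged
  across abstracts, with 1.0 when nothing was marked anywhere.

Undefined ratios (zero denominators) are reported as `NA`, never silently
as 0 or 1.

## Aggregation conventions

All frequency tables count abstracts, not mentions; an abstract with several
distinct themes counts once under each. The corpus-wide denominator is the
number of abstracts with at least one extracted theme; within-category
breakdowns use the category's abstract count; annual series use the themed
abstracts of each year (zero-denominator years are flagged). Percentages use
**half-up rounding** at the reported precision (`round_half_up()`, with an
epsilon guard against binary representation error); the packaged
`reported_percentages()` fixtures contain only published
count/denominator/percent triples consistent with that convention, as a
minority of the published figures round inconsistently (apparent
truncation) and cannot be matched by any single rule.

## The synthetic-data generator

No corpus accession exists for this task, so the generator is a first-class
module: it emits MEDLINE-format corpora whose abstracts are assembled from
anchor-bearing template sentences rendering planted themes, plus distractor
sentences (a dictionary term with *no* anchor — a false-positive probe) and
filler sentences free of dictionary terms. Gold annotations are emitted
alongside. Noise channels mirror the documented error classes:

* `unknown_term_rate` renders a planted concept through a term absent from
  the lexicon. Its intended canonical goes to a sidecar FN ledger rather
  than the gold file (gold stays within the lexicon's canonical set);
  recall measured against gold ∪ ledger is `1 − q` up to binomial error.
* `synonym_rate` renders plants through non-canonical surfaces, stressing
  standardization.
* `distractor_rate` plants unlicensed dictionary terms; a correct extractor
  returns none of them, reproducing the requirement that extraction needs
  pattern licensing.

Defaults emulate the observed composition of the real retrieval: 47% of
abstracts without an extractable theme, about two themes per themed abstract
(Poisson, clamped to 1–5), synonym rate 0.2, and a country pool whose
income mix matches the published output shares (~85% high income, ~6%
upper-middle, ~4% lower-middle, ~1% low, ~4% no affiliated country). The
generator checks at run time that the lexicon does not collide with its
template scaffolds, and that the supplied rule set actually licenses its
templates, so user-supplied resources keep the noise-free contract
(F1 = 1.0).

What the generator does **not** emulate: real scientific prose — nominal
compounds spanning clause boundaries, hedging, anaphora, unstructured
abstracts, and concepts "described far from a simple term". Perfect scores
on synthetic corpora therefore validate the *mechanics* (matching, slot
logic, unification, arithmetic), not real-world recall, which for the
original system was materially below 1 and limited mainly by dictionary and
rule coverage.

Problem sizes used by the test-suite and the acceptance script — 200
abstracts for the noise-free contract, 500 for each recall-under-noise
check, 25–30 random texts of up to 50 tokens against the brute-force
gazetteer oracle, and exhaustive pred/gold enumeration over four themes —
were chosen to put binomial error well inside the three-standard-deviation
acceptance bands while keeping a full run in tens of seconds.

## Degenerate inputs and numerical details

* Empty text: no sentences, no mentions; empty corpora produce empty (not
  malformed) tables.
* An abstract with no year is never dropped by year exclusion and never
  counted in annual series.
* `percent(x, 0)` is `NA`; annual proportions with a zero denominator are 0
  with a flag, so trend plots are drawable.
* Mention output order is fully deterministic (sentence, rule order, anchor
  position, term position); ties in frequency tables break alphabetically.
* Ambiguous lexicons (one surface, two canonicals) and malformed rule files
  fail at load time with the offending surface or rule named.

## Known limitations

* The seed lexicon and 16-rule set are a faithful *method* re-creation, not
  a content reproduction; corpus-scale headline counts from the original
  retrieval are version-dependent and out of scope.
* No negation or hedge detection, no dependency parsing, no learned
  extraction — by design, matching the original method.
* Affiliation parsing handles the conventional "…, City, Country" layout
  and common aliases; exotic affiliation formats fall back to "unknown".
* Determinant vs outcome roles are deliberately not distinguished; the
  abstract-level unification pools both.
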