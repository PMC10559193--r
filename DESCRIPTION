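Package: thememiner
Title: Rule-Based Extraction of Research Themes from Epidemiological
    Criminology Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the study determinants and outcomes ("themes") of
    epidemiological criminology studies from PubMed/MEDLINE abstracts with a
    rule-based method: a curated gazetteer (dictionary) supplies candidate
    theme mentions and anchor patterns built on semi-frozen lexical
    expressions (e.g. "is a risk factor for") license their extraction.
    Includes theme standardization and abstract-level unification, mapping of
    themes to stakeholder research-priority categories, World Bank income-group
    stratification by first-author country, abstract-level precision/recall/F1
    evaluation against gold annotations, corpus aggregation and trend
    reporting, and a seeded synthetic-corpus generator with planted themes and
    gold files for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
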