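flat_fixture <- function() {
  c("PMID- 101",
    "DP  - 2005 Mar",
    "TI  - A cohort of released prisoners.",
    "AB  - Criminality is a risk factor for severe injury. Follow-up",
    "      continued for five years.",
    "AD  - School of Population Health, University of New South Wales, Sydney, Australia.",
    "",
    "PMID- 102",
    "DP  - 2011",
    "TI  - A citation without an abstract.",
    "AD  - College of Medicine, University of Lagos, Lagos, Nigeria.",
    "",
    "PMID- 103",
    "DP  - 1999 Jan-Feb",
    "TI  - Screening in remand centres.",
    "AB  - The prevalence of HPC was high.",
    "")
}

test_that("MEDLINE flat records parse with continuations and missing fields", {
  f <- withr::local_tempfile(fileext = ".medline")
  writeLines(flat_fixture(), f)
  recs <- parse_medline(f)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$pmid, c("101", "102", "103"))
  expect_equal(recs$year, c(2005L, 2011L, 1999L))
  expect_match(recs$text[1], "Follow-up continued for five years\\.$")
  expect_equal(recs$text[2], "") # no AB tag -> empty abstract
})

test_that("PubMed XML parses to the same record shape", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    "<PubmedArticleSet>",
    " <PubmedArticle><MedlineCitation><PMID>201</PMID>",
    "  <Article>",
    "   <Journal><JournalIssue><PubDate><Year>2018</Year></PubDate></JournalIssue></Journal>",
    "   <ArticleTitle>An XML record.</ArticleTitle>",
    "   <Abstract><AbstractText>Criminality is a risk factor for severe injury.</AbstractText></Abstract>",
    "   <AuthorList><Author>",
    "    <AffiliationInfo><Affiliation>Institute of Health, Oslo, Norway.</Affiliation></AffiliationInfo>",
    "   </Author></AuthorList>",
    "  </Article></MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"
  ), f)
  recs <- parse_medline(f)
  expect_equal(recs$pmid, "201")
  expect_equal(recs$year, 2018L)
  expect_match(recs$text, "risk factor")
  expect_match(recs$affiliation, "Norway")
})

test_that("write_medline / parse_medline round-trips core fields", {
  f <- withr::local_tempfile(fileext = ".medline")
  writeLines(flat_fixture(), f)
  recs <- parse_medline(f)
  f2 <- withr::local_tempfile(fileext = ".medline")
  write_medline(recs, f2)
  recs2 <- parse_medline(f2)
  expect_equal(recs2[c("pmid", "year", "title", "text")],
               recs[c("pmid", "year", "title", "text")])
})

test_that("corpus filtering partitions the input and conserves counts", {
  f <- withr::local_tempfile(fileext = ".medline")
  writeLines(flat_fixture(), f)
  recs <- parse_medline(f)
  out <- filter_corpus(recs, exclude_years = 2011)
  expect_equal(out$tally[["n_input"]], 3L)
  # record 102 has no abstract; it is dropped for that reason, not its year
  expect_equal(out$dropped_no_abstract$pmid, "102")
  expect_equal(nrow(out$dropped_year), 0)
  expect_equal(sort(c(out$kept$pmid, out$dropped_no_abstract$pmid,
                      out$dropped_year$pmid)), sort(recs$pmid))
  out2 <- filter_corpus(recs, exclude_years = 1999)
  expect_equal(out2$dropped_year$pmid, "103")
  expect_equal(out2$tally[["n_kept"]] + out2$tally[["n_no_abstract"]] +
                 out2$tally[["n_year_excluded"]], 3L)
  empty <- filter_corpus(recs[0, ])
  expect_equal(unname(empty$tally), rep(0L, 4))
})

test_that("countries come from the rightmost geoname of the affiliation", {
  tab <- default_income_table()
  expect_equal(
    extract_countries("School of Population Health, University of New South Wales, Sydney, Australia.", tab)[[1]],
    "Australia")
  expect_equal(extract_countries("Dept of Criminology, University of York, York, UK.", tab)[[1]],
               "United Kingdom")
  # US state university containing another country's name is not misattributed
  expect_equal(extract_countries("Department of Sociology, University of Georgia, Athens, GA, USA.", tab)[[1]][1],
               "United States")
  expect_equal(extract_countries("", tab)[[1]], character())
})

test_that("income classification uses the four World Bank groups", {
  tab <- default_income_table()
  expect_equal(classify_income(list("Australia"), tab), "high")
  expect_equal(classify_income(list("Malawi"), tab), "low")
  expect_equal(classify_income(list("India"), tab), "lower-middle")
  expect_equal(classify_income(list("Brazil"), tab), "upper-middle")
  expect_equal(classify_income(list(character()), tab), "unknown")
  expect_warning(g <- classify_income(list("Atlantis"), tab), "Atlantis")
  expect_equal(g, "unknown")
  # aliases resolve to their canonical row's group
  expect_equal(classify_income(list("UK"), tab), "high")
})

test_that("themes TSV round-trips pmid, year and theme sets", {
  ct <- tibble::tibble(
    pmid = c("1", "2"), year = c(2001L, 2002L),
    country = c("Australia", ""), income_group = c("high", "unknown"),
    themes = list(c("HIV", "recidivism"), character()),
    mention_count = c(3L, 0L)
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_themes(ct, f)
  back <- read_themes(f)
  expect_equal(back$pmid, ct$pmid)
  expect_equal(back$year, ct$year)
  expect_equal(back$themes, ct$themes)
})
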