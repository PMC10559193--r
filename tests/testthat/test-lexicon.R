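test_that("synonym rows share a canonical and duplicates collapse", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "surface\tcanonical\tcategory",
    "HIV\tHIV\t",
    "AIDS\tHIV\t",
    "human immunodeficiency virus\tHIV\t",
    "human immunodeficiency virus\tHIV\t", # exact duplicate row
    "depression\tdepression\t",
    "depressive disorder\tdepression\t"
  ), f)
  lex <- load_lexicon(f)
  expect_equal(nrow(lex$entries), 5)
  expect_setequal(lex$entries$canonical[lex$entries$surface %in%
                                          c("HIV", "AIDS", "human immunodeficiency virus")],
                  rep("HIV", 3))
  expect_equal(standardize_theme("depressive disorder", lex), "depression")
})

test_that("ambiguous surfaces and empty files are load errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("surface\tcanonical\tcategory", "x\tA\t", "x\tB\t"), f)
  expect_error(load_lexicon(f), "x")
  writeLines(c("# only a comment"), f)
  expect_error(load_lexicon(f), "empty")
  expect_error(lexicon("term", ""), "canonical")
})

test_that("lexicon round-trips through TSV", {
  lex <- tiny_lexicon()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, f)
  lex2 <- load_lexicon(f)
  expect_equal(lex$entries, lex2$entries)
})

test_that("scanning is leftmost-longest on token boundaries", {
  lex <- tiny_lexicon()
  m <- scan_terms("criminality is a risk factor for severe injury", lex)
  expect_equal(m$surface_text, c("criminality", "severe injury"))
  # embedded "injury" inside "severe injury" is not returned
  expect_false("injury" %in% m$surface)
  expect_equal(nrow(scan_terms("no relevant terms here", lex)), 0)
  # two surfaces of one canonical both match
  m2 <- scan_terms("HPC and hepatitis C were discussed", lex)
  expect_equal(nrow(m2), 2)
  expect_equal(unique(m2$canonical), "hepatitis C")
})

test_that("matching tolerates plurals but respects exact acronyms and hyphens", {
  lex <- tiny_lexicon()
  expect_equal(scan_terms("substance uses were compared", lex)$canonical,
               "substance use")
  expect_equal(scan_terms("several rearrest events", lexicon("rearrests", "rearrests"))$canonical,
               "rearrests")
  # "AIDS" is auto-exact: lowercase "aids" must not match
  expect_equal(nrow(scan_terms("hearing aids were provided", lex)), 0)
  expect_equal(scan_terms("AIDS was studied", lex)$canonical, "HIV")
  # hyphen is word-internal: "alcohol" must not match inside "alcohol-involved"
  expect_equal(nrow(scan_terms("alcohol-involved offending",
                               lexicon("alcohol", "alcohol"))), 0)
  # multiword terms never skip sentence punctuation
  expect_equal(nrow(scan_terms("hepatitis. C was measured",
                               lexicon("hepatitis C", "hepatitis C",
                                       complete_canonicals = FALSE))), 0)
})

test_that("scan agrees with a brute-force all-substrings matcher", {
  lex <- tiny_lexicon()
  vocab <- c("criminality", "severe", "injury", "hepatitis", "C", "HPC",
             "HIV", "aids", "recidivism", "substance", "use", "alcohol",
             "the", "of", "and", "study", "prisons", "rates", "injuries")
  set.seed(42)
  for (i in 1:30) {
    txt <- random_text(vocab, max_tokens = 50)
    got <- scan_terms(txt, lex)
    want <- oracle_scan(txt, lex)
    expect_equal(got$start, want$start, info = txt)
    expect_equal(got$end, want$end, info = txt)
    expect_equal(got$canonical, want$canonical, info = txt)
  }
})

test_that("no returned match is a proper sub-span of another", {
  lex <- tiny_lexicon()
  set.seed(7)
  vocab <- c("severe", "injury", "hepatitis", "C", "substance", "use", "of")
  for (i in 1:20) {
    m <- scan_terms(random_text(vocab), lex)
    if (nrow(m) < 2) next
    for (a in seq_len(nrow(m))) {
      inside <- m$start >= m$start[a] & m$end <= m$end[a]
      expect_equal(sum(inside), 1L)
    }
  }
})

test_that("scanning a sentence-joined concatenation is the union of parts", {
  lex <- tiny_lexicon()
  t1 <- "Criminality was frequent among those with severe injury"
  t2 <- "HPC and hepatitis C were both recorded"
  joint <- paste0(t1, ". ", t2)
  m1 <- scan_terms(t1, lex)
  m2 <- scan_terms(t2, lex)
  mj <- scan_terms(joint, lex)
  shift <- nchar(t1) + 2L
  expect_equal(mj$start, c(m1$start, m2$start + shift))
  expect_equal(mj$canonical, c(m1$canonical, m2$canonical))
})
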