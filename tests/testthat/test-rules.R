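test_that("sentence splitting handles boundaries, decimals and abbreviations", {
  s <- split_sentences("A study. Of prisoners.")
  expect_equal(nrow(s), 2)
  expect_equal(s$text, c("A study.", "Of prisoners."))
  expect_equal(nrow(split_sentences("")), 0)
  expect_equal(nrow(split_sentences("Prevalence was 4.5 per 100.")), 1)
  expect_equal(nrow(split_sentences("Rates rose (e.g. In remand). Then fell.")), 2)
  expect_equal(nrow(split_sentences("Dr. Smith reported it. It was confirmed.")), 2)
  # sentences are disjoint, ordered, and substrings of the input
  txt <- "First result here. Second one follows! Third ends."
  s3 <- split_sentences(txt)
  expect_equal(s3$text, thememiner::span_str(txt, s3$start, s3$end))
  expect_true(all(diff(s3$start) > 0))
  expect_true(all(s3$end[-nrow(s3)] <= s3$start[-1]))
})

test_that("rule files validate and round-trip bit-exactly", {
  rs <- tiny_rules()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_rules(rs, f1)
  rs2 <- compile_rules(f1)
  expect_equal(rs2$rules, rs$rules)
  write_rules(rs2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("malformed rules are rejected with the offending rule named", {
  bad_regex <- list(list(id = "r1", anchor = "(unclosed",
                         slots = list(list(side = "right"))))
  expect_error(rule_set(bad_regex), "r1")
  unknown_field <- list(list(id = "r1", anchor = "x", weight = 2,
                             slots = list(list(side = "right"))))
  expect_error(rule_set(unknown_field), "unknown field")
  dup_ids <- list(
    list(id = "r1", anchor = "x", slots = list(list(side = "right"))),
    list(id = "r1", anchor = "y", slots = list(list(side = "left")))
  )
  expect_error(rule_set(dup_ids), "duplicate")
  no_slots <- list(list(id = "r1", anchor = "x", slots = list()))
  expect_error(rule_set(no_slots), "slot")
})

test_that("anchors license nearby dictionary terms; unlicensed terms are dropped", {
  lex <- tiny_lexicon()
  rs <- tiny_rules()
  m <- extract_mentions("Criminality is a risk factor for severe injury.", rs, lex)
  expect_setequal(unique(m$canonical), c("criminality", "severe injury"))
  # dictionary term with no anchor in its sentence: nothing extracted
  expect_equal(nrow(extract_mentions("Prisons contain people.", rs, lex)), 0)
  # coordination: terms reached across "and" count toward one slot
  m2 <- extract_mentions(
    "Predictors of recidivism included substance use and alcohol use.", rs, lex)
  expect_setequal(unique(m2$canonical),
                  c("recidivism", "substance use", "alcohol use"))
})

test_that("extraction is sentence-bounded", {
  lex <- tiny_lexicon()
  rs <- tiny_rules()
  # anchor in sentence 1 must not license the term in sentence 2
  m <- extract_mentions("Predictors of outcome were unclear. Criminality was common.",
                        rs, lex)
  expect_equal(nrow(m), 0)
  txt <- "Criminality is a risk factor for severe injury. The prevalence of HPC was high."
  m2 <- extract_mentions(txt, rs, lex)
  sents <- split_sentences(txt)
  for (i in seq_len(nrow(m2))) {
    s <- sents[m2$sentence_index[i], ]
    expect_true(m2$start[i] >= s$start && m2$end[i] <= s$end)
  }
})

test_that("adding rules never removes mentions; removing entries never adds", {
  lex <- tiny_lexicon()
  rs <- tiny_rules()
  txt <- "The prevalence of HPC was high. Criminality is a risk factor for severe injury."
  base <- extract_mentions(txt, rs, lex)
  grown <- rule_set(c(rs$rules, list(
    list(id = "extra", anchor = "\\bwas\\s+high\\b",
         slots = list(list(side = "left", max_token_gap = 6,
                           allow_coordination = TRUE)))
  )))
  m_grown <- extract_mentions(txt, grown, lex)
  key <- function(m) paste(m$canonical, m$start, m$end, m$rule_id)
  expect_true(all(key(base) %in% key(m_grown)))

  ent <- tiny_lexicon()$entries
  keep <- ent$surface != "criminality"
  smaller <- lexicon(ent$surface[keep], ent$canonical[keep])
  m_small <- extract_mentions(txt, rs, smaller)
  expect_true(all(paste(m_small$canonical, m_small$start) %in%
                    paste(base$canonical, base$start)))
})

test_that("extraction is deterministic", {
  lex <- tiny_lexicon()
  rs <- tiny_rules()
  txt <- "Predictors of recidivism included substance use and alcohol use. Criminality is a risk factor for severe injury."
  expect_identical(extract_mentions(txt, rs, lex), extract_mentions(txt, rs, lex))
})

test_that("the within slot licenses terms inside the anchor span only when it matches", {
  lex <- lexicon(c("alcohol use", "school connectedness", "sanctions"),
                 c("alcohol use", "school connectedness", "sanctions"))
  rs <- default_rules()
  m <- extract_mentions("The effect of alcohol use on school connectedness was examined.",
                        rs, lex)
  expect_setequal(unique(m$canonical), c("alcohol use", "school connectedness"))
  # incomplete frame (no "on"): nothing licensed, even inside "effect of ..."
  m2 <- extract_mentions("The effect of more severe sanctions was debated.", rs, lex)
  expect_equal(nrow(m2), 0)
})

test_that("anchor inventory lists each rule once", {
  expect_equal(nrow(list_anchor_inventory(tiny_rules())), 3)
  expect_equal(nrow(list_anchor_inventory(rule_set(list()))), 0)
  expect_gte(nrow(list_anchor_inventory(default_rules())), 15)
})
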