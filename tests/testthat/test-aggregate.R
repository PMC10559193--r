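test_that("percent uses half-up rounding at the requested precision", {
  expect_equal(percent(1493, 11814), 12.64)
  expect_equal(percent(47, 91, digits = 0), 52)
  expect_equal(round_half_up(2.5, 0), 3) # not banker's rounding
  expect_equal(round_half_up(-2.5, 0), -3)
  expect_equal(percent(1, 0), NA_real_)
})

test_that("theme frequencies count abstracts over the themed denominator", {
  corpus <- tibble::tibble(
    pmid = c("1", "2", "3"),
    year = c(2000L, 2000L, 2001L),
    income_group = "high",
    themes = list(c("A", "B"), "A", character())
  )
  tf <- theme_frequencies(corpus)
  expect_equal(tf$label, c("A", "B"))
  expect_equal(tf$count, c(2L, 1L))
  expect_equal(unique(tf$denominator), 2L) # abstracts with >= 1 theme
  expect_equal(tf$percent, c(100, 50))
  expect_equal(nrow(theme_frequencies(corpus[0, ])), 0)
  # conservation: each per-theme count <= themed count, sum >= themed count
  expect_true(all(tf$count <= 2))
  expect_gte(sum(tf$count), 2)
})

test_that("category frequencies are multi-label with within-category dedup", {
  sch <- default_scheme()
  corpus <- tibble::tibble(
    pmid = "1", year = 2000L, income_group = "high",
    themes = list(c("HIV", "hepatitis C"))
  )
  cf <- category_frequencies(corpus, sch)
  inf <- cf$categories[cf$categories$label == "Infectious disease and infections", ]
  expect_equal(inf$count, 1L) # counted once despite two infectious themes
  expect_equal(inf$percent, 100)
  # within-category breakdown uses the category count as denominator
  sub <- cf$themes_by_category
  expect_setequal(sub$label[sub$category == "Infectious disease and infections"],
                  c("HIV", "hepatitis C"))
  expect_equal(unique(sub$denominator), 1L)
  # zero-output priority categories are present with count 0
  expect_true("Hygiene" %in% cf$categories$label)
  expect_equal(cf$categories$count[cf$categories$label == "Hygiene"], 0L)
})

test_that("annual proportions are contiguous and zero-filled", {
  corpus <- tibble::tibble(
    pmid = as.character(1:5),
    year = c(2000L, 2000L, 2002L, 2002L, 2002L),
    income_group = "high",
    themes = list("A", c("A", "B"), "B", "B", character())
  )
  ts <- annual_proportions(corpus, c("A", "B"), c(2000, 2002))
  expect_equal(sort(unique(ts$year)), 2000:2002)
  a2000 <- ts[ts$year == 2000 & ts$label == "A", ]
  expect_equal(a2000$proportion, 1) # both themed 2000 abstracts carry A
  b2002 <- ts[ts$year == 2002 & ts$label == "B", ]
  expect_equal(b2002$count, 2L)
  expect_equal(b2002$denominator, 2L) # the empty-theme abstract is excluded
  y2001 <- ts[ts$year == 2001, ]
  expect_true(all(y2001$zero_denominator))
  expect_true(all(y2001$proportion == 0))
  empty <- annual_proportions(corpus[0, ], "A", c(2000, 2001))
  expect_true(all(empty$proportion == 0))
})

test_that("income breakdown separates unknown from the four group denominators", {
  sch <- default_scheme()
  corpus <- tibble::tibble(
    pmid = as.character(1:4),
    year = 2000L,
    income_group = c("high", "high", "low", "unknown"),
    themes = list("HIV", "recidivism", "HIV", "depression")
  )
  ib <- income_breakdown(corpus, sch)
  expect_equal(ib$group_sizes$count[ib$group_sizes$income_group == "high"], 2L)
  expect_equal(unique(ib$group_sizes$denominator), 4L)
  hi <- ib$categories[ib$categories$income_group == "high", ]
  expect_equal(unique(hi$denominator), 2L) # unknown abstracts not in group denominators
  lo <- ib$categories[ib$categories$income_group == "low", ]
  expect_equal(lo$category, "Infectious disease and infections")
  expect_equal(lo$percent, 100)
  unk <- ib$categories[ib$categories$income_group == "unknown", ]
  expect_equal(unk$category, "Mental health") # reported as its own rows
})

test_that("the gap report flags ranked priorities with zero research output", {
  freqs <- tibble::tibble(
    label = c("Mental health", "Hygiene", "Infectious disease and infections"),
    count = c(10L, 0L, 7L)
  )
  pri <- tibble::tibble(
    category = c("Mental health", "Hygiene", "Infectious disease and infections"),
    stakeholder_group = "incarcerated people",
    priority_rank = c(1L, 2L, 3L)
  )
  gr <- gap_report(freqs, pri)
  expect_true(gr$gap[gr$category == "Hygiene"])
  expect_false(any(gr$gap[gr$category != "Hygiene"]))
  expect_equal(gr$output_rank[gr$category == "Mental health"], 1L)
  expect_equal(gr$rank_displacement[gr$category == "Hygiene"], 1L)
  # identical rankings give zero displacement
  aligned <- gap_report(freqs[c(1, 3, 2), ],
                        tibble::tibble(category = c("Mental health",
                                                    "Infectious disease and infections",
                                                    "Hygiene"),
                                       stakeholder_group = "directors",
                                       priority_rank = 1:3))
  expect_equal(aligned$rank_displacement, c(0L, 0L, 0L))
  expect_equal(nrow(gap_report(freqs, pri[0, ])), 0)
})
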