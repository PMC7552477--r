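test_that("index years are the earliest qualifying year, with windows clipped", {
  dx <- tibble::tibble(
    person_id = c("a", "a", "a", "b", "c"),
    year = c(2007, 2003, 2010, 2010, 2005),
    code = c("L40.0", "L40.0", "I21", "M45.1", "J45")
  )
  idx <- assign_index_dates(dx)
  expect_equal(idx$index_year[idx$person_id == "a"], 2003)
  # sub-codes qualify by prefix
  expect_equal(idx$index_year[idx$person_id == "b"], 2010)
  # +/-15 years intersected with follow-up 1998-2014
  expect_equal(idx$window_start[idx$person_id == "b"], 1998)
  expect_equal(idx$window_end[idx$person_id == "b"], 2014)
  # no qualifying diagnosis: excluded with a logged reason
  excl <- attr(idx, "excluded")
  expect_equal(excl$person_id, "c")
  expect_match(excl$reason, "no qualifying")
})

test_that("matching returns exactly 2 controls per stratum with exact keys", {
  reg <- generate_registry(registry_spec(n_cases = 40, n_pool = 160, seed = 2))
  res <- cohort_analysis(reg, seed = 5)
  strata <- res$strata
  counts <- table(strata$stratum, strata$role)
  expect_true(all(counts[, "case"] == 1))
  expect_true(all(counts[, "control"] == 2))
  # exhaustive key scan: all members of a stratum share the four keys
  key_check <- strata |>
    dplyr::group_by(stratum) |>
    dplyr::summarise(
      ok = dplyr::n_distinct(age_at_index) == 1 &
        dplyr::n_distinct(gender) == 1 &
        dplyr::n_distinct(married_coliving) == 1 &
        dplyr::n_distinct(municipality) == 1
    )
  expect_true(all(key_check$ok))
})

test_that("matching is deterministic given a seed and handles forced choices", {
  cases <- tibble::tibble(
    person_id = "case1", index_year = 2005, birth_year = 1960,
    gender = "female", married_coliving = 1, municipality = "M001"
  )
  pool <- tibble::tibble(
    person_id = paste0("p", 1:5),
    birth_year = c(1960, 1960, 1960, 1960, 1950),
    gender = "female", married_coliving = 1, municipality = "M001"
  )
  m1 <- match_controls(cases, pool, seed = 3)
  m2 <- match_controls(cases, pool, seed = 3)
  expect_identical(tibble::as_tibble(m1), tibble::as_tibble(m2))

  forced <- match_controls(cases, pool[c(1, 2, 5), ], seed = 1)
  expect_setequal(forced$person_id[forced$role == "control"], c("p1", "p2"))

  # a case with fewer than 2 exact candidates is dropped and logged
  none <- match_controls(cases, pool[5, , drop = FALSE], seed = 1)
  expect_equal(attr(none, "dropped"), 1)
  expect_equal(attr(none, "dropped_cases"), "case1")
})

test_that("cost eligibility: whole first year, then alive at period start", {
  # dies mid first post-index year: ineligible for that year
  expect_false(cost_eligibility(2005, 2006, death_year = 2006))
  # alive at the start of a later period, dies during it: retained
  expect_true(cost_eligibility(2005, 2008, death_year = 2008))
  # alive throughout
  expect_true(cost_eligibility(2005, 2006, death_year = NA))
  expect_true(cost_eligibility(2005, 2003, death_year = 2010))
  expect_error(cost_eligibility(2005, 2006), "vital status",
               class = "outcomepay_validation_error")
})

test_that("income censoring applies the age, cap and period rules idempotently", {
  expect_true(is.na(censor_income(5000, age = 10)))
  expect_true(is.na(censor_income(300000, age = 40)))
  expect_equal(censor_income(50000, age = 40), 50000)
  expect_true(is.na(censor_income(50000, age = 40, year = 2014)))
  once <- censor_income(c(5000, 300000, 50000), age = c(10, 40, 40))
  twice <- censor_income(once, age = c(10, 40, 40))
  expect_identical(once, twice)
})

test_that("ICD-10 codes map onto the 22 WHO chapters", {
  expect_equal(icd10_chapter(c("A09", "B20", "C50", "D22", "D64", "E11")),
               c(1L, 1L, 2L, 2L, 3L, 4L))
  expect_equal(icd10_chapter(c("H25", "H65", "L40.0", "M45", "T14", "V01", "U07")),
               c(7L, 8L, 12L, 13L, 19L, 20L, 22L))
  expect_true(is.na(icd10_chapter("9xx")))
})

test_that("chapter pooling uses the ±3-year window and the 2001-2011 restriction", {
  dx <- tibble::tibble(
    person_id = c("a", "a", "b"),
    year = c(2003, 2009, 2000),
    code = c("I21", "E11", "F32"),
    role = c("secondary", "main", "main")
  )
  idx <- tibble::tibble(person_id = c("a", "b"), index_year = c(2005, 1999))
  flags <- pool_who_chapters(dx, idx)
  # index 1999 excluded from the comorbidity analysis
  expect_false("b" %in% flags$person_id)
  expect_match(attr(flags, "excluded")$reason, "2001-2011")
  a <- flags[flags$person_id == "a", ]
  expect_equal(a$ch09, 1L) # secondary diagnosis 2 years pre-index counts
  expect_equal(a$ch04, 0L) # 4 years post-index: outside the window
  expect_equal(a$ch05, 0L)
})

test_that("conditional logistic contrasts agree with a direct likelihood oracle", {
  lo <- rep(0.5, 22)
  reg <- generate_registry(registry_spec(n_cases = 300, n_pool = 700,
                                         comorbidity_log_odds = lo, seed = 17))
  res <- cohort_analysis(reg, seed = 18)
  dat <- dplyr::inner_join(
    dplyr::select(res$strata, stratum, person_id, role),
    res$chapter_flags, by = "person_id"
  )
  for (ch in c(3, 9, 20)) {
    b_oracle <- oracle_clogit(dat$stratum, as.integer(dat$role == "case"),
                              dat[[sprintf("ch%02d", ch)]])
    b_pkg <- res$contrast$log_or[res$contrast$chapter == ch]
    expect_equal(b_pkg, b_oracle, tolerance = 1e-4)
  }
})

test_that("null planted comorbidity gives odds ratios near 1 with covering CIs", {
  reg <- generate_registry(registry_spec(n_cases = 250, n_pool = 600,
                                         comorbidity_log_odds = rep(0, 22),
                                         seed = 23))
  res <- cohort_analysis(reg, seed = 24)
  # qualifying psoriasis/PsA codes live in chapters 12 and 13; exclude them
  est <- dplyr::filter(res$contrast, !chapter %in% c(12, 13), status == "ok")
  covers <- est$conf_low <= 1 & est$conf_high >= 1
  expect_gte(mean(covers), 0.9)
  expect_lt(mean(abs(est$log_or)), 0.15)
})

test_that("an all-concordant chapter is reported as inestimable", {
  strata <- tibble::tibble(
    stratum = rep(1:3, each = 3),
    person_id = sprintf("p%d", 1:9),
    role = rep(c("case", "control", "control"), 3)
  )
  flags <- tibble::tibble(person_id = sprintf("p%d", 1:9), index_year = 2005)
  for (ch in 1:22) flags[[sprintf("ch%02d", ch)]] <- 0L
  flags$ch01 <- 1L # everyone exposed: concordant everywhere
  out <- chapter_contrast(strata, flags)
  expect_true(all(out$status == "inestimable"))
  expect_true(all(is.na(out$odds_ratio)))
})
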