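test_that("all three generators are deterministic under a fixed seed", {
  p1 <- generate_population(population_spec(n_patients = 100, seed = 7))
  p2 <- generate_population(population_spec(n_patients = 100, seed = 7))
  expect_identical(p1, p2)

  r1 <- generate_registry(registry_spec(n_cases = 20, n_pool = 60, seed = 7))
  r2 <- generate_registry(registry_spec(n_cases = 20, n_pool = 60, seed = 7))
  expect_identical(r1$persons, r2$persons)
  expect_identical(r1$person_years, r2$person_years)
  expect_identical(r1$diagnoses, r2$diagnoses)

  s1 <- generate_sortings(sorting_spec(seed = 7))
  s2 <- generate_sortings(sorting_spec(seed = 7))
  expect_identical(s1$sortings, s2$sortings)
  expect_identical(s1$ratings, s2$ratings)

  p3 <- generate_population(population_spec(n_patients = 100, seed = 8))
  expect_false(identical(p1$pasi_actual, p3$pasi_actual))
})

test_that("generated values respect their defined ranges", {
  pop <- generate_population(population_spec(n_patients = 500, seed = 3))
  expect_true(all(pop$pasi_before >= 0 & pop$pasi_before <= 72))
  expect_true(all(pop$pasi_actual >= 0 & pop$pasi_actual <= 72))
  w <- cbind(pop$weight_1, pop$weight_2)
  expect_true(all(w >= 0))
  expect_true(all(abs(rowSums(w) - 1) < 1e-9))

  srt <- generate_sortings(sorting_spec(seed = 3))
  expect_true(all(srt$ratings$rating %in% 1:5))

  reg <- generate_registry(registry_spec(n_cases = 20, n_pool = 60, seed = 3))
  expect_true(all(reg$person_years$annual_cost >= 0))
  expect_true(all(!duplicated(paste(reg$person_years$person_id,
                                    reg$person_years$year))))
})

test_that("zero outcome noise makes actual PASI equal the linear predictor", {
  spec <- population_spec(n_patients = 50, outcome_noise_sd = 0, seed = 5)
  pop <- generate_population(spec)
  eta <- expected_pasi(pop, spec$true_coefficients)
  expect_equal(pop$pasi_actual, pmin(pmax(eta, 0), 72), tolerance = 1e-12)
})

test_that("planted regression coefficients are recoverable by OLS refit", {
  truth <- prediction_coefficients(1, 0.6, 1, 0.5,
                                   c(age_decades = 0.15, gender_male = 0.3))
  pop <- generate_population(population_spec(
    n_patients = 5000, true_coefficients = truth, outcome_noise_sd = 2, seed = 42
  ))
  # independent oracle: plain least squares on the generated table
  km <- rowSums(as.matrix(pop[paste0("comorb_", 1:5)]))
  ols <- lm(pasi_actual ~ pasi_before + I(obesity + smoking) + km +
              I(age / 10) + I(gender == "male"), data = pop)
  expect_lt(abs(coef(ols)[["pasi_before"]] - 0.6), 0.05)
})

test_that("every case in a generated registry has at least 2 exact-key candidates", {
  reg <- generate_registry(registry_spec(n_cases = 10, n_pool = 40, seed = 1))
  cases <- dplyr::filter(reg$persons, is_case)
  pool <- dplyr::filter(reg$persons, !is_case)
  for (r in seq_len(nrow(cases))) {
    cs <- cases[r, ]
    n_cand <- sum(
      pool$birth_year == cs$birth_year &
        pool$gender == cs$gender &
        pool$married_coliving == cs$married_coliving &
        pool$municipality == cs$municipality
    )
    expect_gte(n_cand, 2)
  }
})

test_that("a zero cost effect leaves case and control mean costs equal", {
  reg <- generate_registry(registry_spec(
    n_cases = 150, n_pool = 400, cost_effect = 0, seed = 9
  ))
  costs <- dplyr::inner_join(
    reg$person_years,
    dplyr::select(reg$persons, person_id, is_case),
    by = "person_id"
  )
  case_costs <- costs$annual_cost[costs$is_case]
  ctrl_costs <- costs$annual_cost[!costs$is_case]
  delta <- mean(case_costs) - mean(ctrl_costs)
  se <- sqrt(var(case_costs) / length(case_costs) +
               var(ctrl_costs) / length(ctrl_costs))
  expect_lt(abs(delta), 3 * se)
})

test_that("a positive cost effect shifts case costs after the index year", {
  reg <- generate_registry(registry_spec(
    n_cases = 150, n_pool = 400, cost_effect = 2000, seed = 9
  ))
  post <- dplyr::inner_join(
    reg$person_years,
    dplyr::select(reg$persons, person_id, is_case, reference_year),
    by = "person_id"
  ) |>
    dplyr::filter(year >= reference_year)
  delta <- mean(post$annual_cost[post$is_case]) -
    mean(post$annual_cost[!post$is_case])
  expect_gt(delta, 1000)
})

test_that("perfect sort fidelity reproduces the planted partition for everyone", {
  srt <- generate_sortings(sorting_spec(sort_fidelity = 1, seed = 4))
  truth <- srt$statements$true_cluster
  for (p in unique(srt$sortings$participant_id)) {
    sub <- dplyr::filter(srt$sortings, participant_id == p)
    piles <- sub$pile_id[match(srt$statements$statement_id, sub$statement_id)]
    expect_true(same_partition(piles, truth))
  }
})

test_that("invalid specs are rejected with the field named", {
  expect_error(population_spec(n_patients = 0), "n_patients",
               class = "outcomepay_validation_error")
  expect_error(population_spec(n_outcome_goals = 1), "n_outcome_goals",
               class = "outcomepay_validation_error")
  expect_error(population_spec(outcome_noise_sd = -1), "outcome_noise_sd",
               class = "outcomepay_validation_error")
  expect_error(registry_spec(n_cases = 30, n_pool = 50), "n_pool",
               class = "outcomepay_validation_error")
  expect_error(registry_spec(comorbidity_log_odds = 1:5), "comorbidity_log_odds",
               class = "outcomepay_validation_error")
  expect_error(sorting_spec(n_statements = 5, n_true_clusters = 9),
               "n_true_clusters", class = "outcomepay_validation_error")
  expect_error(sorting_spec(sort_fidelity = 1.4), "sort_fidelity",
               class = "outcomepay_validation_error")
})
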