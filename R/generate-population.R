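#' Generate a synthetic treated-patient population
#'
#' Draws a patient table with the statistical structure the payment models
#' assume: pre-treatment PASI from a truncated-at-0 normal (capped at the
#' PASI maximum of 72), obesity/smoking flags, five comorbidity indicators,
#' age and gender, department assignment, actual post-treatment PASI generated
#' from the spec's true coefficients plus zero-mean noise (clamped to
#' \[0, 72\]), per-patient actual values on each sub-outcome goal (correlated
#' with the patient's PASI improvement), and Dirichlet(1, ..., 1) importance
#' weights summing to 1.
#'
#' Output is byte-identical for identical specs (one global seed, streamed to
#' sub-draws in fixed order).
#'
#' @param spec A [population_spec()].
#' @return A tibble with one row per patient: `patient_id`, `department_id`,
#'   `age`, `gender`, `obesity`, `smoking`, `comorb_1..5`, `pasi_before`,
#'   `pasi_actual`, `goal_<i>_actual` and `weight_<i>` for each goal.
#' @examples
#' pop <- generate_population(population_spec(n_patients = 20, seed = 7))
#' @export
generate_population <- function(spec) {
  if (!inherits(spec, "population_spec")) {
    stop_invalid("spec", "must be a population_spec")
  }
  n <- spec$n_patients
  I <- spec$n_outcome_goals
  withr::with_seed(spec$seed, {
    patients <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      department_id = sprintf("D%02d", sample(spec$n_departments, n, replace = TRUE)),
      age = round(runif(n, 20, 80)),
      gender = sample(c("female", "male"), n, replace = TRUE),
      obesity = rbinom(n, 1, 0.4),
      smoking = rbinom(n, 1, 0.35)
    )
    for (j in 1:5) {
      patients[[paste0("comorb_", j)]] <- rbinom(n, 1, 0.3)
    }
    patients$pasi_before <- pmin(
      truncnorm::rtruncnorm(n, a = 0, mean = spec$pasi_before_mean,
                            sd = spec$pasi_before_sd),
      72
    )
    eta <- expected_pasi(patients, spec$true_coefficients)
    noise <- if (spec$outcome_noise_sd > 0) rnorm(n, 0, spec$outcome_noise_sd) else 0
    patients$pasi_actual <- pmin(pmax(eta + noise, 0), 72)

    # Sub-outcome goals: level correlated with the patient's PASI improvement
    # (bigger drop => better outcome-goal result), plus independent noise.
    improvement <- patients$pasi_before - patients$pasi_actual
    z_imp <- if (pop_sd(improvement) > 0) {
      (improvement - mean(improvement)) / pop_sd(improvement)
    } else {
      rep(0, n)
    }
    rho <- spec$goal_correlation
    for (i in seq_len(I)) {
      eps <- rnorm(n)
      patients[[sprintf("goal_%d_actual", i)]] <-
        5 + 2 * (rho * z_imp + sqrt(1 - rho^2) * eps)
    }
    w <- matrix(rgamma(n * I, shape = 1), nrow = n)
    w <- w / rowSums(w)
    for (i in seq_len(I)) {
      patients[[sprintf("weight_%d", i)]] <- w[, i]
    }
    patients
  })
}

#' Extract goal actuals, expecteds, or weights as a matrix
#'
#' Convenience accessors for the wide `goal_<i>_actual` / `goal_<i>_expected`
#' / `weight_<i>` column families of a patient table.
#'
#' @param patients Patient table.
#' @param what One of `"actual"`, `"expected"`, `"weight"`.
#' @return Numeric matrix, patients by goals.
#' @keywords internal
goal_matrix <- function(patients, what = c("actual", "expected", "weight")) {
  what <- match.arg(what)
  pattern <- switch(what,
    actual = "^goal_[0-9]+_actual$",
    expected = "^goal_[0-9]+_expected$",
    weight = "^weight_[0-9]+$"
  )
  cols <- grep(pattern, names(patients), value = TRUE)
  idx <- as.integer(gsub("[^0-9]", "", cols))
  as.matrix(patients[cols[order(idx)]])
}
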