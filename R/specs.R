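#' Specification for a synthetic treated-patient population
#'
#' Describes the population that [generate_population()] draws: cohort size,
#' department structure, the number of patient-prioritised outcome goals, the
#' pre-treatment PASI distribution, and the "true" linear-model coefficients
#' used to generate post-treatment PASI (so that downstream coefficient fits
#' can be checked against a known truth).
#'
#' @param n_patients Number of patients.
#' @param n_departments Number of hospital departments patients are spread over.
#' @param n_outcome_goals Number of sub-outcome goals per patient (at least 2).
#' @param pasi_before_mean,pasi_before_sd Mean and SD of the truncated-at-0
#'   normal distribution of pre-treatment PASI (PASI lives on \[0, 72\]).
#' @param true_coefficients A [prediction_coefficients()] object used to
#'   generate the actual post-treatment PASI.
#' @param outcome_noise_sd Nonnegative SD of the noise added to the linear
#'   predictor when generating actual post-treatment PASI.
#' @param goal_correlation Correlation between a patient's PASI improvement and
#'   their outcome-goal levels, so that the standardized-deviation projection
#'   of anticipated sub-outcomes has signal to work with.
#' @param seed Integer seed; a spec is fully reproducible given its seed.
#'
#' @return An object of class `population_spec`.
#' @seealso [generate_population()]
#' @export
population_spec <- function(n_patients = 200,
                            n_departments = 4,
                            n_outcome_goals = 2,
                            pasi_before_mean = 12,
                            pasi_before_sd = 6,
                            true_coefficients = default_coefficients(),
                            outcome_noise_sd = 2,
                            goal_correlation = 0.5,
                            seed = 1L) {
  spec <- list(
    n_patients = check_positive_int(n_patients, "n_patients"),
    n_departments = check_positive_int(n_departments, "n_departments"),
    n_outcome_goals = check_positive_int(n_outcome_goals, "n_outcome_goals"),
    pasi_before_mean = check_number(pasi_before_mean, "pasi_before_mean", min = 0, max = 72),
    pasi_before_sd = check_number(pasi_before_sd, "pasi_before_sd", min = 0),
    true_coefficients = true_coefficients,
    outcome_noise_sd = check_number(outcome_noise_sd, "outcome_noise_sd", min = 0),
    goal_correlation = check_number(goal_correlation, "goal_correlation", min = -1, max = 1),
    seed = as.integer(check_number(seed, "seed"))
  )
  if (spec$n_outcome_goals < 2) {
    stop_invalid("n_outcome_goals", "at least 2 outcome goals are required")
  }
  if (!inherits(true_coefficients, "prediction_coefficients")) {
    stop_invalid("true_coefficients", "must be a prediction_coefficients object")
  }
  structure(spec, class = "population_spec")
}

#' Specification for a synthetic person-level registry
#'
#' Describes the case/control registry that [generate_registry()] draws:
#' numbers of cases and of potential controls, the calendar follow-up window,
#' and the planted case-vs-control effects (an additive annual-cost shift and
#' per-WHO-chapter comorbidity log-odds) that downstream contrasts should
#' recover.
#'
#' @param n_cases Number of case patients (each receives a qualifying
#'   psoriasis/PsA diagnosis at an index year).
#' @param n_pool Number of potential controls; must be at least `2 * n_cases`
#'   so that full 1:2 matching is possible by construction.
#' @param year_range Length-2 integer vector, first and last calendar year of
#'   follow-up.
#' @param cost_effect Additive shift (EUR/year) applied to cases' annual costs
#'   from their index year onward.
#' @param comorbidity_log_odds Length-22 vector of case excess log-odds of
#'   carrying a diagnosis in each WHO ICD-10 chapter within the comorbidity
#'   window.
#' @param index_year_range Length-2 vector of calendar years the case index
#'   years are drawn from.
#' @param case_codes Character vector of qualifying diagnosis codes planted at
#'   cases' index years.
#' @param seed Integer seed.
#'
#' @return An object of class `registry_spec`.
#' @seealso [generate_registry()]
#' @export
registry_spec <- function(n_cases = 200,
                          n_pool = 800,
                          year_range = c(1998L, 2014L),
                          cost_effect = 1500,
                          comorbidity_log_odds = rep(0.35, 22),
                          index_year_range = c(2001L, 2011L),
                          case_codes = default_case_codes(),
                          seed = 1L) {
  spec <- list(
    n_cases = check_positive_int(n_cases, "n_cases"),
    n_pool = check_positive_int(n_pool, "n_pool"),
    year_range = as.integer(year_range),
    cost_effect = check_number(cost_effect, "cost_effect"),
    comorbidity_log_odds = comorbidity_log_odds,
    index_year_range = as.integer(index_year_range),
    case_codes = as.character(case_codes),
    seed = as.integer(seed)
  )
  if (spec$n_pool < 2L * spec$n_cases) {
    stop_invalid("n_pool", "must be at least 2 * n_cases for full 1:2 matching")
  }
  if (length(spec$year_range) != 2 || diff(spec$year_range) < 1) {
    stop_invalid("year_range", "must be two increasing calendar years")
  }
  if (!is.numeric(spec$comorbidity_log_odds) || length(spec$comorbidity_log_odds) != 22) {
    stop_invalid("comorbidity_log_odds", "must be a length-22 numeric vector (WHO chapters)")
  }
  if (spec$index_year_range[1] < spec$year_range[1] ||
      spec$index_year_range[2] > spec$year_range[2]) {
    stop_invalid("index_year_range", "must lie within year_range")
  }
  structure(spec, class = "registry_spec")
}

#' Default qualifying diagnosis codes
#'
#' The hospital-diagnosis code lists for plaque/guttate psoriasis and
#' psoriatic arthritis used as the default case definition: L40.0, L40.4
#' (PsO), L40.5, M07.0-M07.3, M45 (PsA).
#'
#' @return Character vector of ICD-10 codes.
#' @export
default_case_codes <- function() {
  c("L40.0", "L40.4", "L40.5", "M07.0", "M07.1", "M07.2", "M07.3", "M45")
}

#' Specification for synthetic card-sort data
#'
#' Describes the focus-group card-sorting exercise that [generate_sortings()]
#' draws: participants pile statements, and a planted cluster structure with a
#' controllable fidelity governs how often a statement lands in its "true"
#' pile. Participants also rate each statement's importance on a 1-5 scale,
#' with per-cluster mean levels.
#'
#' @param n_statements Number of statements to sort.
#' @param n_participants Number of focus-group participants. The default, 12,
#'   matches two focus groups of six patients each.
#' @param n_true_clusters Number of planted clusters (at most `n_statements`).
#' @param sort_fidelity Probability in \[0, 1\] that a participant piles a
#'   statement with its true cluster.
#' @param rating_means Length-`n_true_clusters` vector of mean importance
#'   ratings (on the 1-5 scale) per cluster; recycled if length 1.
#' @param rating_sd SD of the latent rating before rounding/clipping to 1-5.
#' @param seed Integer seed.
#'
#' @return An object of class `sorting_spec`.
#' @seealso [generate_sortings()]
#' @export
sorting_spec <- function(n_statements = 40,
                         n_participants = 12,
                         n_true_clusters = 7,
                         sort_fidelity = 0.9,
                         rating_means = NULL,
                         rating_sd = 0.7,
                         seed = 1L) {
  spec <- list(
    n_statements = check_positive_int(n_statements, "n_statements"),
    n_participants = check_positive_int(n_participants, "n_participants"),
    n_true_clusters = check_positive_int(n_true_clusters, "n_true_clusters"),
    sort_fidelity = check_number(sort_fidelity, "sort_fidelity", min = 0, max = 1),
    rating_sd = check_number(rating_sd, "rating_sd", min = 0),
    seed = as.integer(seed)
  )
  if (spec$n_true_clusters > spec$n_statements) {
    stop_invalid("n_true_clusters", "cannot exceed n_statements")
  }
  if (is.null(rating_means)) {
    rating_means <- seq(2.5, 4.5, length.out = spec$n_true_clusters)
  }
  if (length(rating_means) == 1) {
    rating_means <- rep(rating_means, spec$n_true_clusters)
  }
  if (length(rating_means) != spec$n_true_clusters ||
      any(rating_means < 1) || any(rating_means > 5)) {
    stop_invalid("rating_means", "must be per-cluster values in [1, 5]")
  }
  spec$rating_means <- as.numeric(rating_means)
  structure(spec, class = "sorting_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    "<population_spec> %d patients, %d departments, %d outcome goals (seed %d)\n",
    x$n_patients, x$n_departments, x$n_outcome_goals, x$seed
  ))
  invisible(x)
}

#' @export
print.registry_spec <- function(x, ...) {
  cat(sprintf(
    "<registry_spec> %d cases, %d pool, follow-up %d-%d (seed %d)\n",
    x$n_cases, x$n_pool, x$year_range[1], x$year_range[2], x$seed
  ))
  invisible(x)
}

#' @export
print.sorting_spec <- function(x, ...) {
  cat(sprintf(
    "<sorting_spec> %d statements, %d participants, %d planted clusters, fidelity %.2f (seed %d)\n",
    x$n_statements, x$n_participants, x$n_true_clusters, x$sort_fidelity, x$seed
  ))
  invisible(x)
}
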