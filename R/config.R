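# Known configuration keys per block; unknown keys are rejected, not ignored.
config_schema <- function() {
  list(
    seed = NULL,
    output_dir = NULL,
    log_level = NULL,
    synthetic = list(
      population = c("n_patients", "n_departments", "n_outcome_goals",
                     "pasi_before_mean", "pasi_before_sd", "outcome_noise_sd",
                     "goal_correlation", "seed"),
      registry = c("n_cases", "n_pool", "year_range", "cost_effect",
                   "comorbidity_log_odds", "index_year_range", "case_codes",
                   "seed"),
      sorting = c("n_statements", "n_participants", "n_true_clusters",
                  "sort_fidelity", "rating_means", "rating_sd", "seed")
    ),
    coefficients = c("beta0", "beta1", "beta2", "beta3", "beta4_age_decades",
                     "beta4_gender_male"),
    remuneration = c("budget_limit", "productivity_rate", "k", "model"),
    cohort = c("case_codes", "age_band"),
    simulation = c("rounds", "effort_sdlog"),
    conceptmap = c("n_clusters")
  )
}

check_keys <- function(block, allowed, path) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key: %s", paste0(path, unknown[1])),
          class = "outcomepay_config_error")
  }
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration with per-module blocks (`synthetic`,
#' `coefficients`, `remuneration`, `cohort`, `simulation`, `conceptmap`,
#' plus top-level `seed`, `output_dir`, `log_level`). Unknown keys anywhere
#' in the file are rejected with the offending key named, so typos cannot
#' silently change an analysis.
#'
#' @param path Path to a YAML file.
#' @return Named list of validated configuration blocks, class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("configuration file not found: %s", path),
          class = "outcomepay_config_error")
  }
  cfg <- yaml::read_yaml(path)
  schema <- config_schema()
  check_keys(cfg, names(schema), "")
  if (!is.null(cfg$synthetic)) {
    check_keys(cfg$synthetic, names(schema$synthetic), "synthetic.")
    for (blk in names(schema$synthetic)) {
      if (!is.null(cfg$synthetic[[blk]])) {
        check_keys(cfg$synthetic[[blk]], schema$synthetic[[blk]],
                   paste0("synthetic.", blk, "."))
      }
    }
  }
  for (blk in c("coefficients", "remuneration", "cohort", "simulation",
                "conceptmap")) {
    if (!is.null(cfg[[blk]])) {
      check_keys(cfg[[blk]], schema[[blk]], paste0(blk, "."))
    }
  }
  structure(cfg, class = "run_config")
}

#' Coefficients to and from YAML
#'
#' Round-trips a [prediction_coefficients()] object through the
#' `coefficients:` block of a configuration file.
#'
#' @param coefficients A [prediction_coefficients()] object.
#' @param path File to write / read.
#' @return `write_coefficients()` returns the path invisibly;
#'   `read_coefficients()` returns a [prediction_coefficients()] object.
#' @export
write_coefficients <- function(coefficients, path) {
  yaml::write_yaml(list(coefficients = list(
    beta0 = coefficients$beta0, beta1 = coefficients$beta1,
    beta2 = coefficients$beta2, beta3 = coefficients$beta3,
    beta4_age_decades = unname(coefficients$beta4[["age_decades"]]),
    beta4_gender_male = unname(coefficients$beta4[["gender_male"]])
  )), path)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  cfg <- yaml::read_yaml(path)
  coefficients_from_config(cfg$coefficients %||% cfg)
}

coefficients_from_config <- function(block) {
  check_keys(block, config_schema()$coefficients, "coefficients.")
  prediction_coefficients(
    beta0 = block$beta0, beta1 = block$beta1,
    beta2 = block$beta2, beta3 = block$beta3,
    beta4 = c(age_decades = block$beta4_age_decades %||% 0,
              gender_male = block$beta4_gender_male %||% 0)
  )
}

population_spec_from_config <- function(block, seed = NULL,
                                        coefficients = default_coefficients()) {
  block <- block %||% list()
  args <- block
  args$true_coefficients <- coefficients
  if (!is.null(seed) && is.null(args$seed)) args$seed <- seed
  do.call(population_spec, args)
}

registry_spec_from_config <- function(block, seed = NULL) {
  block <- block %||% list()
  if (!is.null(seed) && is.null(block$seed)) block$seed <- seed
  do.call(registry_spec, block)
}

sorting_spec_from_config <- function(block, seed = NULL) {
  block <- block %||% list()
  if (!is.null(seed) && is.null(block$seed)) block$seed <- seed
  do.call(sorting_spec, block)
}
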