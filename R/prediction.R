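#' Coefficients of the anticipated-PASI linear model
#'
#' The anticipated PASI after treatment for patient p is the linear predictor
#'
#' \deqn{PS_{p,Exp} = \beta_0 + \beta_1 PS_{p,Bef} + \beta_2 KR_p +
#'   \beta_3 KM_p + \beta_4 BG_p}
#'
#' where `PS_Bef` is pre-treatment PASI, `KR` counts the obesity/smoking
#' lifestyle flags (0-2), `KM` counts comorbidities, and `BG` holds background
#' covariates. `BG` is encoded here as a two-slot vector (age in decades, male
#' indicator), each with its own coefficient; the single symbol beta4 in the
#' model statement is a vector under this convention.
#'
#' @param beta0 Intercept.
#' @param beta1 Coefficient on pre-treatment PASI.
#' @param beta2 Coefficient on the obesity + smoking count (KR, 0-2).
#' @param beta3 Coefficient on the comorbidity count (KM).
#' @param beta4 Named length-2 vector with elements `age_decades` and
#'   `gender_male`, the background-covariate (BG) coefficients.
#'
#' @return An object of class `prediction_coefficients`.
#' @export
prediction_coefficients <- function(beta0, beta1, beta2, beta3,
                                    beta4 = c(age_decades = 0, gender_male = 0)) {
  vals <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3, beta4)
  if (any(!is.finite(vals))) {
    stop_invalid("coefficients", "all coefficients must be finite")
  }
  if (length(beta4) != 2 || !all(c("age_decades", "gender_male") %in% names(beta4))) {
    stop_invalid("beta4", "must be a named vector with `age_decades` and `gender_male`")
  }
  structure(
    list(
      beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
      beta2 = as.numeric(beta2), beta3 = as.numeric(beta3),
      beta4 = c(
        age_decades = as.numeric(beta4[["age_decades"]]),
        gender_male = as.numeric(beta4[["gender_male"]])
      )
    ),
    class = "prediction_coefficients"
  )
}

#' Default "true" generating coefficients
#'
#' A mildly optimistic treatment response: anticipated post-treatment PASI
#' rises with pre-treatment severity (slope 0.55), lifestyle risk factors,
#' comorbidity burden, age, and male gender. Chosen so that the linear
#' predictor stays within the PASI range for realistic covariates.
#'
#' @return A [prediction_coefficients()] object.
#' @export
default_coefficients <- function() {
  prediction_coefficients(
    beta0 = 1, beta1 = 0.55, beta2 = 1, beta3 = 0.5,
    beta4 = c(age_decades = 0.15, gender_male = 0.3)
  )
}

#' @export
print.prediction_coefficients <- function(x, ...) {
  cat("<prediction_coefficients>\n")
  print(unlist(x))
  invisible(x)
}

# Design matrix columns for the anticipated-PASI model, derived from a
# patient table's raw covariates.
model_covariates <- function(patients) {
  check_columns(
    patients,
    c("pasi_before", "obesity", "smoking", "age", "gender"),
    "patients"
  )
  comorb_cols <- grep("^comorb_", names(patients), value = TRUE)
  km <- if (length(comorb_cols) > 0) {
    rowSums(as.matrix(patients[comorb_cols]))
  } else if ("n_comorbidities" %in% names(patients)) {
    patients$n_comorbidities
  } else {
    stop_invalid("patients", "needs comorb_* columns or n_comorbidities")
  }
  tibble::tibble(
    pasi_before = patients$pasi_before,
    kr = patients$obesity + patients$smoking,
    km = km,
    age_decades = patients$age / 10,
    gender_male = as.numeric(patients$gender == "male")
  )
}

#' Anticipated PASI after treatment
#'
#' Evaluates the anticipated-PASI linear predictor for each patient. The
#' result is the raw linear predictor: it is deliberately not clipped to the
#' PASI range \[0, 72\], because the payment formulas consume differences of
#' anticipated and actual PASI and clipping would silently distort them.
#'
#' @param patients Patient table with columns `pasi_before`, `obesity`,
#'   `smoking`, `age`, `gender`, and either `comorb_*` indicator columns or an
#'   `n_comorbidities` count.
#' @param coefficients A [prediction_coefficients()] object.
#'
#' @return Numeric vector of anticipated PASI values, one per row.
#' @examples
#' pts <- tibble::tibble(
#'   pasi_before = 10, obesity = 0, smoking = 0,
#'   n_comorbidities = 0, age = 0, gender = "female"
#' )
#' expected_pasi(pts, prediction_coefficients(1, 0.5, 0, 0))
#' @export
expected_pasi <- function(patients, coefficients) {
  if (!inherits(coefficients, "prediction_coefficients")) {
    stop_invalid("coefficients", "must be a prediction_coefficients object")
  }
  x <- model_covariates(patients)
  coefficients$beta0 +
    coefficients$beta1 * x$pasi_before +
    coefficients$beta2 * x$kr +
    coefficients$beta3 * x$km +
    coefficients$beta4[["age_decades"]] * x$age_decades +
    coefficients$beta4[["gender_male"]] * x$gender_male
}

#' Fit the anticipated-PASI model by least squares
#'
#' In deployment the model coefficients come from literature estimates; on
#' synthetic data they are refit here by ordinary least squares of actual
#' post-treatment PASI on pre-treatment PASI, the lifestyle count, the
#' comorbidity count and the background covariates, so that parameter
#' recovery against the generator's planted truth is testable.
#'
#' @param patients Patient table with the covariates of [expected_pasi()] plus
#'   `pasi_actual`.
#' @return An object of class `pasi_fit`; access the coefficients with
#'   `coef()`/`$coefficients` (a [prediction_coefficients()] object) and
#'   inspect the fit with [tidy()] and [glance()].
#' @export
fit_coefficients <- function(patients) {
  check_columns(patients, "pasi_actual", "patients")
  x <- model_covariates(patients)
  p <- ncol(x) + 1L
  if (nrow(patients) < p + 1L) {
    abort(sprintf(
      "at least %d patients are needed to fit %d coefficients", p + 1L, p
    ), class = "outcomepay_validation_error")
  }
  dat <- dplyr::mutate(x, pasi_actual = patients$pasi_actual)
  fit <- lm(pasi_actual ~ pasi_before + kr + km + age_decades + gender_male, data = dat)
  est <- coef(fit)
  if (anyNA(est)) {
    abort(sprintf(
      "rank-deficient design: collinear column(s) %s",
      paste(names(est)[is.na(est)], collapse = ", ")
    ), class = "outcomepay_validation_error")
  }
  structure(
    list(
      fit = fit,
      coefficients = prediction_coefficients(
        beta0 = est[["(Intercept)"]], beta1 = est[["pasi_before"]],
        beta2 = est[["kr"]], beta3 = est[["km"]],
        beta4 = c(
          age_decades = est[["age_decades"]],
          gender_male = est[["gender_male"]]
        )
      ),
      n = nrow(patients)
    ),
    class = "pasi_fit"
  )
}

#' @export
coef.pasi_fit <- function(object, ...) object$coefficients

#' @export
print.pasi_fit <- function(x, ...) {
  cat(sprintf("<pasi_fit> anticipated-PASI model fit on %d patients\n", x$n))
  print(unlist(x$coefficients))
  invisible(x)
}

#' @rdname fit_coefficients
#' @param x,object A `pasi_fit`.
#' @param ... Unused.
#' @export
tidy.pasi_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("beta0", "beta1", "beta2", "beta3", "beta4_age_decades", "beta4_gender_male"),
    covariate = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p_value = s[, "Pr(>|t|)"]
  )
}

#' @rdname fit_coefficients
#' @export
glance.pasi_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    n = x$n
  )
}

#' Standardized deviation of a patient's anticipated PASI
#'
#' Places each patient within the spread of anticipated PASI across all
#' patients, as the deviation from the mean expressed in population (1/n)
#' standard deviations:
#'
#' \deqn{Deviation_p = \frac{PS_{p,Exp} - \mu}{\sqrt{\frac{1}{n}\sum_p
#'   (PS_{p,Exp} - \mu)^2}}}
#'
#' @param patient_expected Anticipated PASI value(s) to standardize
#'   (vectorized).
#' @param all_expected Anticipated PASI of all patients in the system; needs
#'   at least 2 values with nonzero spread.
#'
#' @return Numeric vector of standardized deviations.
#' @examples
#' standardized_deviation(14, c(10, 14)) # +1
#' @export
standardized_deviation <- function(patient_expected, all_expected) {
  if (length(all_expected) < 2) {
    stop_invalid("all_expected", "needs at least 2 values")
  }
  s <- pop_sd(all_expected)
  if (s == 0) {
    abort("standardization undefined: anticipated PASI has zero spread",
          class = "outcomepay_degenerate_error")
  }
  (patient_expected - mean(all_expected)) / s
}

#' Project a standardized deviation onto an outcome goal
#'
#' Anticipates a patient's result on a sub-outcome goal by assuming they
#' deviate from the mean of all patients' actual results in the same way
#' (in SD units) as their anticipated PASI deviates from its mean:
#'
#' \deqn{o_{i,p,Exp} = Deviation_p \cdot \sqrt{\frac{1}{n}\sum_p
#'   (o_{i,p,Act} - \mu_{o_i})^2} + \mu_{o_i}}
#'
#' A patient anticipated one SD below the PASI mean is anticipated one SD
#' below the mean on every outcome goal.
#'
#' @param deviation Standardized deviation(s) from [standardized_deviation()].
#' @param outcome_actuals_all Actual values of the outcome goal across all
#'   patients; needs at least 2 values.
#'
#' @return Anticipated outcome value(s).
#' @examples
#' project_expected_outcome(1, c(2, 5, 8)) # mean 5, pop SD ~2.45
#' @export
project_expected_outcome <- function(deviation, outcome_actuals_all) {
  if (length(outcome_actuals_all) < 2) {
    stop_invalid("outcome_actuals_all", "needs at least 2 values")
  }
  deviation * pop_sd(outcome_actuals_all) + mean(outcome_actuals_all)
}

#' Anticipate PASI, deviations and outcome goals for a population
#'
#' Runs the full anticipation pipeline on a patient table: the anticipated
#' PASI linear predictor, each patient's standardized deviation within the
#' system-wide spread, and the projected anticipated value of every
#' sub-outcome goal.
#'
#' @param patients Patient table as produced by [generate_population()]
#'   (columns `goal_<i>_actual` hold actual sub-outcome results).
#' @param coefficients A [prediction_coefficients()] object.
#'
#' @return The patient table with added columns `pasi_expected`, `deviation`,
#'   and `goal_<i>_expected` for each goal.
#' @export
anticipate_outcomes <- function(patients, coefficients) {
  patients <- tibble::as_tibble(patients)
  exp_pasi <- expected_pasi(patients, coefficients)
  dev <- standardized_deviation(exp_pasi, exp_pasi)
  out <- dplyr::mutate(patients, pasi_expected = exp_pasi, deviation = dev)
  goal_cols <- grep("^goal_[0-9]+_actual$", names(patients), value = TRUE)
  for (col in goal_cols) {
    exp_col <- sub("_actual$", "_expected", col)
    out[[exp_col]] <- project_expected_outcome(dev, patients[[col]])
  }
  out
}
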