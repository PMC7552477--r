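#' Remuneration configuration
#'
#' Bundles the knobs of the value-based payment scheme: the total budget
#' limit X that the payout must respect, the productivity rate used to derive
#' X from a department budget (the discontinued annual 2% productivity
#' requirement is replaced by a value-based pool of the same size), the
#' scaling factor k (or `"auto"` to calibrate it against X), and which payment
#' model to use: `"A"` (PASI-difference with patient-priority correction) or
#' `"B"` (weighted outcome-goal differences).
#'
#' @param budget_limit Total value-based budget limit X (> 0).
#' @param productivity_rate Fraction of a department budget earmarked for
#'   value-based payment; default 0.02.
#' @param k Positive scaling factor, or `"auto"` to calibrate via
#'   [calibrate_k()] so that total payout equals X.
#' @param model `"A"` or `"B"`.
#'
#' @return An object of class `remuneration_config`.
#' @export
remuneration_config <- function(budget_limit, productivity_rate = 0.02,
                                k = "auto", model = c("B", "A")) {
  model <- match.arg(model)
  budget_limit <- check_number(budget_limit, "budget_limit")
  if (budget_limit <= 0) stop_invalid("budget_limit", "must be > 0")
  productivity_rate <- check_number(productivity_rate, "productivity_rate", 0, 1)
  if (!identical(k, "auto")) {
    k <- check_number(k, "k")
    if (k <= 0) stop_invalid("k", "must be > 0 when explicit")
  }
  structure(
    list(budget_limit = budget_limit, productivity_rate = productivity_rate,
         k = k, model = model),
    class = "remuneration_config"
  )
}

#' @export
print.remuneration_config <- function(x, ...) {
  cat(sprintf(
    "<remuneration_config> model %s, X = %g, k = %s, productivity rate %.3f\n",
    x$model, x$budget_limit,
    if (identical(x$k, "auto")) "auto" else format(x$k), x$productivity_rate
  ))
  invisible(x)
}

#' Patient-priority correction factor alpha
#'
#' The correction factor multiplying the PASI-difference payment, reflecting
#' how well the treatment served the outcome goals the patient personally
#' weighted highly. For two goals it is
#'
#' \deqn{\alpha_p = \frac{O_1 w_1 + O_2 w_2}{(O_1 + O_2)/2}}
#'
#' generalized here to I goals as the weighted mean of the per-goal changes
#' over their unweighted mean. alpha > 1 when the highly weighted goals
#' improved more than average; alpha = 1 when weights are equal or all goals
#' changed equally, in which case the payment reduces to the pure
#' PASI-difference form.
#'
#' @param outcome_deltas Length-I (I >= 2) vector of per-goal outcome changes
#'   O_i, oriented so larger = better.
#' @param weights Length-I nonnegative weights summing to 1.
#'
#' @return The scalar correction factor.
#' @examples
#' compute_alpha(c(2, 2), c(0.5, 0.5)) # 1
#' compute_alpha(c(4, 1), c(0.8, 0.2)) # 1.36
#' @export
compute_alpha <- function(outcome_deltas, weights) {
  if (length(outcome_deltas) < 2) {
    stop_invalid("outcome_deltas", "at least 2 outcome goals are required")
  }
  if (length(weights) != length(outcome_deltas)) {
    stop_invalid("weights", "must match outcome_deltas in length")
  }
  check_weights(weights)
  denom <- mean(outcome_deltas)
  if (denom == 0) {
    abort("alpha undefined: unweighted mean of outcome changes is zero",
          class = "outcomepay_degenerate_error")
  }
  sum(outcome_deltas * weights) / denom
}

#' Model A payment for one patient
#'
#' Pays for a better-than-anticipated PASI, corrected by the patient-priority
#' factor and scaled by k:
#'
#' \deqn{Afl_p = (PS_{p,Exp} - PS_{p,Act}) \cdot \alpha_p \cdot k}
#'
#' Positive when the patient ends better (lower PASI) than anticipated,
#' negative otherwise; the sign is retained here — flooring of negative
#' values happens at calibration/payout time.
#'
#' @param expected_pasi,actual_pasi Anticipated and actual post-treatment
#'   PASI (vectorized).
#' @param alpha Patient-priority correction factor(s), > 0.
#' @param k Positive scaling factor.
#'
#' @return Payment value(s).
#' @examples
#' model_a_payment(12, 8, alpha = 1.36, k = 10) # 54.4
#' @export
model_a_payment <- function(expected_pasi, actual_pasi, alpha = 1, k) {
  if (any(k <= 0)) stop_invalid("k", "must be > 0")
  if (any(alpha <= 0)) stop_invalid("alpha", "must be > 0")
  (expected_pasi - actual_pasi) * alpha * k
}

#' Model B patient value
#'
#' The unscaled value created for one patient: the weighted sum of
#' better-than-anticipated changes across the patient's sub-outcome goals
#' (the inner sum of the Model B payment formula),
#'
#' \deqn{\sum_{i=1}^I w_{i,p} (o_{i,p,Act} - o_{i,p,Exp})}
#'
#' with outcome goals oriented so larger = better.
#'
#' @param actual_outcomes,expected_outcomes Length-I vectors of actual and
#'   anticipated sub-outcome results.
#' @param weights Length-I nonnegative weights summing to 1.
#'
#' @return Scalar patient value (multiply by k for the payment).
#' @examples
#' patient_value_b(c(4, 7), c(2, 3), c(0.5, 0.5)) # 3
#' @export
patient_value_b <- function(actual_outcomes, expected_outcomes, weights) {
  if (length(actual_outcomes) != length(expected_outcomes) ||
      length(actual_outcomes) != length(weights)) {
    stop_invalid("expected_outcomes", "goal vectors must have matching length")
  }
  check_weights(weights)
  sum(weights * (actual_outcomes - expected_outcomes))
}

#' Calibrate the scaling factor k against the budget limit
#'
#' Sets k = X divided by the system-wide sum of patient values, so that the
#' amount paid out can never exceed the total limit X. Negative patient
#' values are floored at 0 before summing: with raw negatives in the
#' denominator the calibration could produce payouts above X or a negative
#' k, contradicting the budget guarantee.
#'
#' @param budget_limit Total budget limit X (> 0).
#' @param patient_values Per-patient values (Model A PASI differences times
#'   alpha, or Model B weighted outcome-goal sums).
#'
#' @return The calibrated scalar k.
#' @examples
#' calibrate_k(100, c(3, 7)) # 10
#' calibrate_k(100, c(3, 7, -5)) # still 10: negatives floored
#' @export
calibrate_k <- function(budget_limit, patient_values) {
  if (budget_limit <= 0) stop_invalid("budget_limit", "must be > 0")
  total <- sum(pmax(patient_values, 0))
  if (total <= 0) {
    abort(
      "calibration undefined: no patient created better-than-anticipated value",
      class = "outcomepay_degenerate_error"
    )
  }
  budget_limit / total
}

#' Department shares of the budget limit
#'
#' Distributes the budget limit X across hospital departments in proportion
#' to the value their patients created beyond anticipation, with negative
#' patient values floored at 0. A department contributing 3 units of a
#' system-wide 10 receives 30% of X; a sole improver receives all of X
#' regardless of how much better than anticipated its outcomes are.
#'
#' @param department_values Data frame with columns `department_id` and
#'   `value` (one row per patient or per department; values are floored at 0
#'   and summed within department).
#' @param budget_limit Total budget limit X.
#'
#' @return A tibble with `department_id`, `value` (floored sum), `share`
#'   (fraction of X), and `payment`.
#' @examples
#' department_share(
#'   tibble::tibble(department_id = c("A", "B"), value = c(3, 7)),
#'   budget_limit = 100
#' )
#' @export
department_share <- function(department_values, budget_limit) {
  check_columns(department_values, c("department_id", "value"), "department_values")
  dept <- department_values |>
    dplyr::mutate(value = pmax(.data$value, 0)) |>
    dplyr::group_by(.data$department_id) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
  total <- sum(dept$value)
  if (total <= 0) {
    abort(
      "calibration undefined: no patient created better-than-anticipated value",
      class = "outcomepay_degenerate_error"
    )
  }
  dplyr::mutate(dept,
    share = .data$value / total,
    payment = .data$share * budget_limit
  )
}

#' Budget limit from a department budget
#'
#' The value-based budget limit replaces the discontinued annual productivity
#' requirement: X = rate × department budget, with the default rate of 2%.
#'
#' @param dept_budget Department budget (> 0).
#' @param rate Fraction in \[0, 1\]; default 0.02.
#'
#' @return The budget limit X.
#' @examples
#' budget_limit_from_department(1e6) # 20000
#' @export
budget_limit_from_department <- function(dept_budget, rate = 0.02) {
  if (any(dept_budget <= 0)) stop_invalid("dept_budget", "must be > 0")
  rate <- check_number(rate, "rate", 0, 1)
  rate * dept_budget
}

#' Remunerate a patient population
#'
#' Runs the full payment pipeline on a patient table: anticipates PASI,
#' deviations and sub-outcome goals via [anticipate_outcomes()], computes
#' each patient's value under the configured model (A: PASI difference times
#' the patient-priority factor alpha; B: weighted sum of outcome-goal
#' differences), calibrates k against the budget limit when `k = "auto"`,
#' floors negative values at payout, and attributes payments to departments.
#'
#' @param patients Patient table as from [generate_population()] (or with
#'   precomputed `pasi_expected`, `deviation` and `goal_<i>_expected`
#'   columns, which are then used as-is).
#' @param config A [remuneration_config()].
#' @param coefficients A [prediction_coefficients()] object (ignored if the
#'   anticipation columns are already present).
#'
#' @return A `payment_ledger`: a tibble with `patient_id`, `department_id`,
#'   `value` (signed), `value_floored`, and `payment`, carrying the
#'   calibrated `k`, the budget limit, the model, and the per-department
#'   summary (see [department_share()]) as attributes; access them with
#'   `attr(ledger, "k")` etc., or summarise with [glance()].
#' @export
remunerate <- function(patients, config, coefficients = default_coefficients()) {
  if (!inherits(config, "remuneration_config")) {
    stop_invalid("config", "must be a remuneration_config")
  }
  patients <- tibble::as_tibble(patients)
  check_columns(patients, c("patient_id", "department_id"), "patients")
  if (!all(c("pasi_expected", "deviation") %in% names(patients)) ||
      length(grep("^goal_[0-9]+_expected$", names(patients))) == 0) {
    patients <- anticipate_outcomes(patients, coefficients)
  }
  act <- goal_matrix(patients, "actual")
  exp_ <- goal_matrix(patients, "expected")
  w <- goal_matrix(patients, "weight")
  deltas <- act - exp_

  value <- if (config$model == "A") {
    alpha <- vapply(seq_len(nrow(patients)), function(r) {
      compute_alpha(deltas[r, ], w[r, ])
    }, numeric(1))
    (patients$pasi_expected - patients$pasi_actual) * alpha
  } else {
    rowSums(w * deltas)
  }

  value_floored <- pmax(value, 0)
  k <- if (identical(config$k, "auto")) {
    calibrate_k(config$budget_limit, value)
  } else {
    config$k
  }
  ledger <- tibble::tibble(
    patient_id = patients$patient_id,
    department_id = patients$department_id,
    value = value,
    value_floored = value_floored,
    payment = value_floored * k
  )
  departments <- department_share(
    tibble::tibble(department_id = ledger$department_id, value = ledger$value),
    config$budget_limit
  )
  structure(
    ledger,
    class = c("payment_ledger", class(ledger)),
    k = k,
    budget_limit = config$budget_limit,
    model = config$model,
    departments = departments
  )
}

#' @rdname remunerate
#' @param x,object A `payment_ledger`.
#' @param ... Unused.
#' @export
glance.payment_ledger <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model"),
    n_patients = nrow(x),
    n_departments = nrow(attr(x, "departments")),
    k = attr(x, "k"),
    budget_limit = attr(x, "budget_limit"),
    total_payout = sum(x$payment),
    n_positive_values = sum(x$value > 0)
  )
}

#' Per-department summary of a payment ledger
#'
#' @param ledger A `payment_ledger` from [remunerate()].
#' @return Tibble with `department_id`, floored `value`, `share`, `payment`.
#' @export
ledger_departments <- function(ledger) {
  attr(ledger, "departments")
}

#' @export
print.payment_ledger <- function(x, ...) {
  cat(sprintf(
    "<payment_ledger> model %s | %d patients | k = %.6g | payout %.2f of limit %.2f\n",
    attr(x, "model"), nrow(x), attr(x, "k"), sum(x$payment), attr(x, "budget_limit")
  ))
  NextMethod()
}
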