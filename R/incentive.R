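#' Behaviour policies for an incentive round
#'
#' A policy assigns each department an effort multiplier applied to its
#' patients' true improvements: 1 reproduces baseline behaviour, 2 doubles
#' every better-than-anticipated change, values below 1 model departments
#' collectively creating less value.
#'
#' @param department_id Character vector of department ids.
#' @param effort_multiplier Positive multiplier per department.
#'
#' @return A tibble with one row per department.
#' @export
behavior_policy <- function(department_id, effort_multiplier = 1) {
  if (any(effort_multiplier <= 0)) {
    stop_invalid("effort_multiplier", "must be > 0")
  }
  tibble::tibble(
    department_id = as.character(department_id),
    effort_multiplier = as.numeric(effort_multiplier)
  )
}

#' Run one remuneration round under behaviour policies
#'
#' Anticipated values (anticipated PASI, standardized deviations, projected
#' sub-outcome goals) are computed on the baseline population and held fixed
#' — the payer's risk adjustment is set ex ante — while each department's
#' effort multiplier scales its patients' realized improvements:
#' `actual = anticipated + m * (actual - anticipated)` for every outcome
#' goal, and symmetrically `PS_Act = PS_Exp - m * (PS_Exp - PS_Act)` on the
#' PASI channel. Payments are then computed with [remunerate()].
#'
#' Holding the anticipation fixed is what makes the scheme's documented
#' "side effect" exact: scaling every improvement by the same c > 0 scales
#' every patient value by c and leaves all department shares unchanged.
#'
#' @param population Patient table from [generate_population()].
#' @param policies A [behavior_policy()] tibble; departments not listed get
#'   multiplier 1.
#' @param config A [remuneration_config()].
#' @param coefficients A [prediction_coefficients()] object.
#' @param seed Optional integer seed (the round itself is deterministic; the
#'   seed is recorded for provenance and future stochastic extensions).
#'
#' @return A `payment_ledger` (see [remunerate()]).
#' @export
run_round <- function(population, policies = NULL, config,
                      coefficients = default_coefficients(), seed = NULL) {
  population <- tibble::as_tibble(population)
  check_columns(population, c("patient_id", "department_id"), "population")
  counts <- table(population$department_id)
  if (any(counts == 0)) {
    stop_invalid("population", "every department must have at least one patient")
  }
  ant <- anticipate_outcomes(population, coefficients)
  m <- rep(1, nrow(ant))
  if (!is.null(policies)) {
    check_columns(policies, c("department_id", "effort_multiplier"), "policies")
    if (any(policies$effort_multiplier <= 0)) {
      stop_invalid("effort_multiplier", "must be > 0")
    }
    unknown <- setdiff(policies$department_id, population$department_id)
    if (length(unknown) > 0) {
      stop_invalid("policies", paste(
        "policy for empty/unknown department(s):",
        paste(unknown, collapse = ", ")
      ))
    }
    idx <- match(ant$department_id, policies$department_id)
    m <- ifelse(is.na(idx), 1, policies$effort_multiplier[idx])
  }
  ant$pasi_actual <- ant$pasi_expected - m * (ant$pasi_expected - ant$pasi_actual)
  goal_cols <- grep("^goal_[0-9]+_actual$", names(ant), value = TRUE)
  for (col in goal_cols) {
    exp_col <- sub("_actual$", "_expected", col)
    ant[[col]] <- ant[[exp_col]] + m * (ant[[col]] - ant[[exp_col]])
  }
  ledger <- remunerate(ant, config, coefficients)
  attr(ledger, "seed") <- seed
  ledger
}

#' Monte-Carlo incentive rounds
#'
#' Repeatedly perturbs department effort (log-normal multipliers) and pays
#' the population, producing the ledgers that [aspect_report()] audits for
#' the scheme's budgetary and incentive properties.
#'
#' @param population Patient table from [generate_population()].
#' @param config A [remuneration_config()].
#' @param coefficients A [prediction_coefficients()] object.
#' @param n_rounds Number of rounds; default 200.
#' @param effort_sdlog SD of the log effort multipliers; default 0.3.
#' @param seed Integer seed for the multiplier draws.
#'
#' @return List of `payment_ledger` objects, one per round.
#' @export
simulate_rounds <- function(population, config,
                            coefficients = default_coefficients(),
                            n_rounds = 200, effort_sdlog = 0.3, seed = 1L) {
  depts <- sort(unique(population$department_id))
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_rounds), function(r) {
      pol <- behavior_policy(depts, rlnorm(length(depts), 0, effort_sdlog))
      run_round(population, pol, config, coefficients, seed = seed)
    })
  })
}

#' Audit incentive rounds against the scheme's three design aspects
#'
#' Tabulates, per ledger: total payout against the budget limit X with an
#' at-limit flag (aspect 1: compliance with an overall financial limit, paid
#' in full whenever any department creates positive value); whether a single
#' department holds all positive value and therefore absorbs the full limit
#' (the sole-improver saturation case); and the department share vectors,
#' from which cross-round share identity is flagged (aspect 3: departments
#' uniformly scaling their created value — collusion — leave every share
#' unchanged, the documented "side effect" of calibrating k system-wide).
#' When the ledgers form an ordered scenario sequence for one department,
#' `focal_department` additionally reports payment-monotonicity violations
#' (aspect 2: more improvement must never pay less).
#'
#' @param ledgers A `payment_ledger` or list of them.
#' @param focal_department Optional department id whose payment is checked
#'   for monotone non-decrease across the ledger sequence.
#'
#' @return An `aspect_report`: list with `rounds` (per-round tibble), `shares`
#'   (round × department share tibble), `collusion_invariant` (TRUE when all
#'   rounds produced identical share vectors within 1e-9), and
#'   `monotonicity_violations` (count, or NA when no focal department given).
#' @export
aspect_report <- function(ledgers, focal_department = NULL) {
  if (inherits(ledgers, "payment_ledger")) ledgers <- list(ledgers)
  if (length(ledgers) < 1) stop_invalid("ledgers", "at least one ledger required")
  rounds <- purrr::imap(ledgers, function(led, i) {
    dept <- ledger_departments(led)
    x <- attr(led, "budget_limit")
    payout <- sum(led$payment)
    tibble::tibble(
      round = i,
      budget_limit = x,
      total_payout = payout,
      payout_at_limit = abs(payout - x) < 1e-9 * max(1, x),
      within_limit = payout <= x + 1e-9 * max(1, x),
      n_positive_values = sum(led$value > 0),
      sole_improver = sum(dept$share > 0) == 1
    )
  }) |> dplyr::bind_rows()
  shares <- purrr::imap(ledgers, function(led, i) {
    dplyr::mutate(ledger_departments(led), round = i)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("round", "department_id", "share") |>
    tidyr::pivot_wider(names_from = "department_id", values_from = "share")
  share_mat <- as.matrix(shares[-1])
  collusion_invariant <- nrow(share_mat) >= 2 &&
    max(abs(sweep(share_mat, 2, share_mat[1, ]))) < 1e-9
  monotonicity_violations <- NA_integer_
  if (!is.null(focal_department)) {
    pay <- vapply(ledgers, function(led) {
      dept <- ledger_departments(led)
      row <- dept$payment[dept$department_id == focal_department]
      if (length(row) == 0) 0 else row
    }, numeric(1))
    monotonicity_violations <- sum(diff(pay) < -1e-9)
  }
  structure(
    list(
      rounds = rounds,
      shares = shares,
      collusion_invariant = collusion_invariant,
      monotonicity_violations = monotonicity_violations
    ),
    class = "aspect_report"
  )
}

#' @export
print.aspect_report <- function(x, ...) {
  cat(sprintf(
    "<aspect_report> %d round(s) | within limit: %d | at limit: %d | share-identical rounds: %s\n",
    nrow(x$rounds), sum(x$rounds$within_limit), sum(x$rounds$payout_at_limit),
    ifelse(isTRUE(x$collusion_invariant), "yes (collusion side effect)", "no")
  ))
  if (!is.na(x$monotonicity_violations)) {
    cat(sprintf("  focal-department monotonicity violations: %d\n",
                x$monotonicity_violations))
  }
  invisible(x)
}
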