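#' Generate a synthetic person-level registry
#'
#' Draws a case/control registry with the structure the matched-cohort
#' pipeline assumes. Cases receive a qualifying psoriasis/PsA diagnosis at an
#' index year drawn from `index_year_range`. The control pool is built so
#' that full 1:2 matching is possible by construction: the first
#' `2 * n_cases` pool members copy, pairwise, the matching keys (birth year,
#' gender, married/co-living, municipality) and reference year of a case;
#' any remaining pool members are drawn independently.
#'
#' Planted case-vs-control effects are recorded for recovery testing: an
#' additive annual-cost shift from the index year onward (`cost_effect`), and
#' per-WHO-chapter excess log-odds of carrying a diagnosis in that chapter
#' within ±3 years of the reference year (`comorbidity_log_odds`).
#'
#' @param spec A [registry_spec()].
#' @return An object of class `synthetic_registry`: a list of three tibbles,
#'   `persons` (one row per person: ids, keys, case status, index/reference
#'   year, death year with `NA` = alive at end of follow-up), `person_years`
#'   (per person-year: age, annual cost, annual income, alive-at-year-start
#'   flag), and `diagnoses` (long: person, year, ICD-10-like code, role in
#'   main/action/secondary).
#' @examples
#' reg <- generate_registry(registry_spec(n_cases = 10, n_pool = 40, seed = 1))
#' @export
generate_registry <- function(spec) {
  if (!inherits(spec, "registry_spec")) {
    stop_invalid("spec", "must be a registry_spec")
  }
  withr::with_seed(spec$seed, {
    n_case <- spec$n_cases
    n_pool <- spec$n_pool
    n <- n_case + n_pool
    y0 <- spec$year_range[1]
    y1 <- spec$year_range[2]

    case_index <- sample(seq(spec$index_year_range[1], spec$index_year_range[2]),
                         n_case, replace = TRUE)
    case_age_at_index <- round(runif(n_case, 10, 85))
    cases <- tibble::tibble(
      person_id = sprintf("C%05d", seq_len(n_case)),
      is_case = TRUE,
      birth_year = case_index - case_age_at_index,
      gender = sample(c("female", "male"), n_case, replace = TRUE),
      married_coliving = rbinom(n_case, 1, 0.6),
      municipality = sprintf("M%03d", sample(50, n_case, replace = TRUE)),
      reference_year = case_index,
      index_year = case_index
    )

    # Tied pool members: two per case, sharing the case's matching keys and
    # reference year, so every case has >= 2 exact-key candidates.
    tied_idx <- rep(seq_len(n_case), each = 2)
    tied <- tibble::tibble(
      person_id = sprintf("K%05d", seq_len(2 * n_case)),
      is_case = FALSE,
      birth_year = cases$birth_year[tied_idx],
      gender = cases$gender[tied_idx],
      married_coliving = cases$married_coliving[tied_idx],
      municipality = cases$municipality[tied_idx],
      reference_year = cases$reference_year[tied_idx],
      index_year = NA_integer_
    )
    n_extra <- n_pool - 2L * n_case
    extra <- if (n_extra > 0) {
      ref <- sample(seq(spec$index_year_range[1], spec$index_year_range[2]),
                    n_extra, replace = TRUE)
      tibble::tibble(
        person_id = sprintf("X%05d", seq_len(n_extra)),
        is_case = FALSE,
        birth_year = ref - round(runif(n_extra, 10, 85)),
        gender = sample(c("female", "male"), n_extra, replace = TRUE),
        married_coliving = rbinom(n_extra, 1, 0.6),
        municipality = sprintf("M%03d", sample(50, n_extra, replace = TRUE)),
        reference_year = ref,
        index_year = NA_integer_
      )
    } else {
      NULL
    }
    persons <- dplyr::bind_rows(cases, tied, extra)

    # Vital status: ~15% die during follow-up, uniformly after their
    # reference year.
    dies <- rbinom(n, 1, 0.15) == 1
    death_year <- rep(NA_integer_, n)
    death_year[dies] <- pmin(
      persons$reference_year[dies] + sample(0:10, sum(dies), replace = TRUE),
      y1
    )
    persons$death_year <- death_year

    # Person-years: follow-up years up to and including the death year.
    person_years <- tidyr::crossing(
      person_id = persons$person_id, year = seq(y0, y1)
    ) |>
      dplyr::left_join(
        dplyr::select(persons, "person_id", "is_case", "birth_year",
                      "reference_year", "death_year"),
        by = "person_id"
      ) |>
      dplyr::filter(is.na(.data$death_year) | .data$year <= .data$death_year) |>
      dplyr::mutate(
        age = .data$year - .data$birth_year,
        alive_at_year_start = is.na(.data$death_year) | .data$year <= .data$death_year
      ) |>
      dplyr::filter(.data$age >= 0)
    m <- nrow(person_years)
    person_years$annual_cost <- rlnorm(m, meanlog = 7, sdlog = 0.6) +
      ifelse(person_years$is_case & person_years$year >= person_years$reference_year,
             spec$cost_effect, 0)
    person_years$annual_income <- rlnorm(m, meanlog = log(32000), sdlog = 0.55)
    person_years <- dplyr::select(
      person_years, "person_id", "year", "age", "annual_cost",
      "annual_income", "alive_at_year_start"
    )

    # Qualifying diagnoses for cases at their index year.
    qualifying <- tibble::tibble(
      person_id = cases$person_id,
      year = cases$index_year,
      code = sample(spec$case_codes, n_case, replace = TRUE),
      role = "main"
    )

    # Comorbidity: per person and WHO chapter, a chronic condition is present
    # with base prevalence per chapter, shifted by the planted log-odds for
    # cases. A present condition generates recurring registry contacts (each
    # follow-up year independently with probability 1/2), so that any ±3-year
    # comorbidity window almost surely captures it, for cases and controls
    # alike, and the planted log-odds are recoverable regardless of how the
    # window is anchored.
    base_prev <- rep(c(0.25, 0.3, 0.35), length.out = 22)
    chapter_rows <- tidyr::crossing(
      idx = seq_len(n), chapter = seq_len(22)
    )
    p <- plogis(
      qlogis(base_prev[chapter_rows$chapter]) +
        ifelse(persons$is_case[chapter_rows$idx],
               spec$comorbidity_log_odds[chapter_rows$chapter], 0)
    )
    present <- rbinom(nrow(chapter_rows), 1, p) == 1
    hit <- chapter_rows[present, ]
    hit$code <- random_chapter_code(hit$chapter)
    years <- seq(y0, y1)
    occ <- tidyr::crossing(hit_row = seq_len(nrow(hit)), year = years)
    occ <- occ[rbinom(nrow(occ), 1, 0.5) == 1, ]
    # guarantee at least one contact per present condition
    first_occ <- tibble::tibble(
      hit_row = seq_len(nrow(hit)),
      year = sample(years, nrow(hit), replace = TRUE)
    )
    occ <- dplyr::distinct(dplyr::bind_rows(occ, first_occ))
    comorbid <- tibble::tibble(
      person_id = persons$person_id[hit$idx[occ$hit_row]],
      year = occ$year,
      code = hit$code[occ$hit_row],
      role = sample(c("main", "action", "secondary"), nrow(occ), replace = TRUE)
    )
    diagnoses <- dplyr::arrange(
      dplyr::bind_rows(qualifying, comorbid),
      .data$person_id, .data$year, .data$code
    )

    structure(
      list(persons = persons, person_years = person_years, diagnoses = diagnoses,
           spec = spec),
      class = "synthetic_registry"
    )
  })
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat(sprintf(
    "<synthetic_registry> %d persons (%d cases), %d person-years, %d diagnoses\n",
    nrow(x$persons), sum(x$persons$is_case), nrow(x$person_years), nrow(x$diagnoses)
  ))
  invisible(x)
}

# A random ICD-10-like code inside each WHO chapter (vectorized over chapter).
random_chapter_code <- function(chapter) {
  # representative (letter, numeric range) per chapter; inverted by
  # icd10_chapter().
  starts <- c("A", "C", "D5", "E", "F", "G", "H0", "H6", "I", "J", "K", "L",
              "M", "N", "O", "P", "Q", "R", "S", "V", "Z", "U")
  lows  <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0)
  highs <- c(99, 97, 9, 90, 99, 99, 59, 95, 99, 99, 93, 99, 99, 99, 99, 96,
             99, 99, 99, 98, 99, 99)
  # two-digit starts (D5, H0, H6) already fix the leading digit
  num <- floor(runif(length(chapter)) *
                 (highs[chapter] - lows[chapter] + 1)) + lows[chapter]
  pre <- starts[chapter]
  ifelse(nchar(pre) == 2,
         sprintf("%s%d", pre, num %% 10),
         sprintf("%s%02d", pre, num))
}
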