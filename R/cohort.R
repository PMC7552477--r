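#' Assign index years to cases
#'
#' A case's index year is the year of their first qualifying diagnosis (first
#' registry contact with a qualifying code). The analysis window is the index
#' year ±15 years intersected with the follow-up range. Persons with no
#' qualifying diagnosis are excluded with a logged reason.
#'
#' @param diagnoses Long diagnosis tibble with `person_id`, `year`, `code`.
#' @param case_codes Character vector of qualifying codes (sub-codes match by
#'   prefix, so `"M45"` also matches `"M45.1"`).
#' @param year_range Length-2 follow-up calendar range; default 1998-2014.
#'
#' @return Tibble with `person_id`, `index_year`, `window_start`,
#'   `window_end`; excluded persons (if any person ids are supplied via the
#'   `persons` attribute of `diagnoses`, none here) are recorded in the
#'   `excluded` attribute as a tibble of `person_id`, `reason`.
#' @export
assign_index_dates <- function(diagnoses, case_codes = default_case_codes(),
                               year_range = c(1998L, 2014L)) {
  check_columns(diagnoses, c("person_id", "year", "code"), "diagnoses")
  pattern <- paste0("^(", paste(gsub("\\.", "\\\\.", case_codes), collapse = "|"), ")")
  qualifying <- dplyr::filter(diagnoses, grepl(pattern, .data$code))
  index <- qualifying |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(index_year = min(.data$year), .groups = "drop") |>
    dplyr::mutate(
      window_start = pmax(.data$index_year - 15L, year_range[1]),
      window_end = pmin(.data$index_year + 15L, year_range[2])
    )
  excluded <- tibble::tibble(
    person_id = setdiff(unique(diagnoses$person_id), index$person_id),
    reason = "no qualifying diagnosis"
  )
  structure(index, excluded = excluded)
}

#' Match controls 1:2 on exact keys
#'
#' For each case, candidate controls are pool members with exactly equal
#' gender, married/co-living status, municipality, and age at the case's
#' index year (optionally banded); two are sampled uniformly without
#' replacement within the run. Cases with fewer than two exact candidates
#' are dropped, with the count logged in the `dropped` attribute.
#'
#' @param cases Tibble with `person_id`, `index_year`, `birth_year`,
#'   `gender`, `married_coliving`, `municipality`.
#' @param pool Tibble of potential controls with `person_id`, `birth_year`,
#'   `gender`, `married_coliving`, `municipality`; must be disjoint from
#'   `cases`.
#' @param seed Integer run seed for candidate sampling.
#' @param age_band Age half-width in whole years for the age key; default 0
#'   (exact age at index).
#'
#' @return Long tibble with one row per stratum member: `stratum`,
#'   `person_id`, `role` (`"case"`/`"control"`), and the matching-key
#'   snapshot (`age_at_index`, `gender`, `married_coliving`, `municipality`).
#'   Attributes: `dropped` (number of cases without 2 candidates),
#'   `dropped_cases` (their ids).
#' @export
match_controls <- function(cases, pool, seed = 1L, age_band = 0L) {
  key_cols <- c("gender", "married_coliving", "municipality")
  check_columns(cases, c("person_id", "index_year", "birth_year", key_cols), "cases")
  check_columns(pool, c("person_id", "birth_year", key_cols), "pool")
  if (length(intersect(cases$person_id, pool$person_id)) > 0) {
    stop_invalid("pool", "must be disjoint from cases")
  }
  withr::with_seed(as.integer(seed), {
    strata <- vector("list", nrow(cases))
    dropped <- character(0)
    used <- character(0)
    for (r in seq_len(nrow(cases))) {
      cs <- cases[r, ]
      case_age <- cs$index_year - cs$birth_year
      cand_age <- cs$index_year - pool$birth_year
      ok <- pool$gender == cs$gender &
        pool$married_coliving == cs$married_coliving &
        pool$municipality == cs$municipality &
        abs(cand_age - case_age) <= age_band &
        !(pool$person_id %in% used)
      cand <- pool$person_id[ok]
      if (length(cand) < 2) {
        dropped <- c(dropped, cs$person_id)
        next
      }
      picked <- if (length(cand) == 2) cand else sample(cand, 2)
      used <- c(used, picked)
      members <- dplyr::bind_rows(
        tibble::tibble(person_id = cs$person_id, role = "case",
                       age_at_index = case_age),
        tibble::tibble(person_id = picked, role = "control",
                       age_at_index = cs$index_year -
                         pool$birth_year[match(picked, pool$person_id)])
      )
      members$stratum <- r
      members$gender <- cs$gender
      members$married_coliving <- cs$married_coliving
      members$municipality <- cs$municipality
      members$index_year <- cs$index_year
      strata[[r]] <- members
    }
    out <- dplyr::bind_rows(strata)
    if (nrow(out) == 0) {
      out <- tibble::tibble(
        stratum = integer(0), person_id = character(0), role = character(0),
        index_year = integer(0), age_at_index = integer(0),
        gender = character(0), married_coliving = numeric(0),
        municipality = character(0)
      )
      return(structure(out, dropped = length(dropped), dropped_cases = dropped))
    }
    out <- dplyr::select(
      out, "stratum", "person_id", "role", "index_year",
      "age_at_index", "gender", "married_coliving", "municipality"
    )
    structure(out, dropped = length(dropped), dropped_cases = dropped)
  })
}

#' Cost-analysis eligibility for a period
#'
#' The first period after the index date requires survival through the whole
#' year; later periods (and pre-index periods) require only being alive at
#' the start of the period — a person who dies mid-period is retained for
#' that period.
#'
#' @param index_year Case index year(s).
#' @param year Calendar year of the period under assessment.
#' @param death_year Death year, `NA` meaning alive through end of follow-up.
#'   Must be supplied explicitly (vital status is required, not optional).
#'
#' @return Logical eligibility flag(s) (vectorized).
#' @examples
#' cost_eligibility(2005, 2006, death_year = 2006) # dies mid first year: FALSE
#' cost_eligibility(2005, 2008, death_year = 2008) # alive at start of year 3: TRUE
#' @export
cost_eligibility <- function(index_year, year, death_year) {
  if (missing(death_year)) {
    stop_invalid("death_year", "vital status is required (use NA for alive)")
  }
  n <- max(length(index_year), length(year), length(death_year))
  index_year <- rep_len(index_year, n)
  year <- rep_len(year, n)
  death_year <- rep_len(death_year, n)
  alive <- is.na(death_year)
  first_period <- year == index_year + 1L
  ifelse(first_period,
         alive | death_year > year,   # whole first post-index year survived
         alive | death_year >= year)  # alive at start of the period
}

#' Censor income values
#'
#' Income is set to missing (not 0) for persons aged 0-15 years and for
#' incomes above 270,000 EUR/year; income analysis is restricted to
#' 1998-2013 (years outside are also set missing). The rules are idempotent
#' and order-independent.
#'
#' @param income Annual income (EUR), vectorized.
#' @param age Age in years.
#' @param year Calendar year of the income; default within range, so the
#'   year rule only bites when supplied.
#'
#' @return Income with censored entries set to `NA`.
#' @examples
#' censor_income(c(5000, 300000, 50000), age = c(10, 40, 40)) # NA NA 50000
#' @export
censor_income <- function(income, age, year = 2000L) {
  n <- max(length(income), length(age), length(year))
  income <- rep_len(income, n)
  age <- rep_len(age, n)
  year <- rep_len(year, n)
  ifelse(age <= 15 | income > 270000 | year < 1998 | year > 2013,
         NA_real_, income)
}

#' WHO chapter of an ICD-10-like code
#'
#' Maps codes to the 22 top-level ICD-10 chapters by letter and two-digit
#' number (A00-B99 = 1, ..., U = 22). Unmappable codes return `NA`.
#'
#' @param code Character vector of codes such as `"L40.0"`, `"I21"`.
#' @return Integer chapter 1-22, or `NA`.
#' @export
icd10_chapter <- function(code) {
  letter <- substr(code, 1, 1)
  num <- suppressWarnings(as.integer(substr(code, 2, 3)))
  dplyr::case_when(
    letter %in% c("A", "B") ~ 1L,
    letter == "C" ~ 2L,
    letter == "D" & !is.na(num) & num <= 48 ~ 2L,
    letter == "D" ~ 3L,
    letter == "E" ~ 4L,
    letter == "F" ~ 5L,
    letter == "G" ~ 6L,
    letter == "H" & !is.na(num) & num <= 59 ~ 7L,
    letter == "H" ~ 8L,
    letter == "I" ~ 9L,
    letter == "J" ~ 10L,
    letter == "K" ~ 11L,
    letter == "L" ~ 12L,
    letter == "M" ~ 13L,
    letter == "N" ~ 14L,
    letter == "O" ~ 15L,
    letter == "P" ~ 16L,
    letter == "Q" ~ 17L,
    letter == "R" ~ 18L,
    letter %in% c("S", "T") ~ 19L,
    letter %in% c("V", "W", "X", "Y") ~ 20L,
    letter == "Z" ~ 21L,
    letter == "U" ~ 22L,
    .default = NA_integer_
  )
}

#' Pool diagnoses onto the 22 WHO chapters
#'
#' For each person, sets a chapter flag when any diagnosis of any role
#' (main, action, or secondary) falls within ±3 years of the person's index
#' year. Because of the symmetric 3-year window inside 1998-2014 follow-up,
#' only index years 2001-2011 are analysable; persons outside that range are
#' excluded with a logged reason, as are unmappable codes.
#'
#' @param diagnoses Long tibble with `person_id`, `year`, `code` (role
#'   optional: all roles count).
#' @param index_years Tibble with `person_id` and `index_year` (for matched
#'   strata, pass the stratum case's index year for every member).
#'
#' @return Wide tibble: `person_id`, `index_year`, `ch01` ... `ch22` (0/1).
#'   Attributes: `excluded` (persons with index outside 2001-2011),
#'   `unmapped` (codes that mapped to no chapter).
#' @export
pool_who_chapters <- function(diagnoses, index_years) {
  check_columns(diagnoses, c("person_id", "year", "code"), "diagnoses")
  check_columns(index_years, c("person_id", "index_year"), "index_years")
  eligible <- dplyr::filter(index_years,
                            .data$index_year >= 2001, .data$index_year <= 2011)
  excluded <- dplyr::anti_join(index_years, eligible, by = "person_id") |>
    dplyr::mutate(reason = "index year outside 2001-2011")
  dx <- dplyr::mutate(diagnoses, chapter = icd10_chapter(.data$code))
  unmapped <- unique(dx$code[is.na(dx$chapter)])
  dx <- dplyr::filter(dx, !is.na(.data$chapter))
  flags_long <- dx |>
    dplyr::inner_join(eligible, by = "person_id", relationship = "many-to-many") |>
    dplyr::filter(abs(.data$year - .data$index_year) <= 3) |>
    dplyr::distinct(.data$person_id, .data$chapter)
  out <- eligible
  for (ch in 1:22) {
    flagged <- flags_long$person_id[flags_long$chapter == ch]
    out[[sprintf("ch%02d", ch)]] <- as.integer(out$person_id %in% flagged)
  }
  structure(out, excluded = excluded, unmapped = unmapped)
}

#' Case-control contrast per WHO chapter
#'
#' Fits, for each of the 22 WHO chapters, a conditional logistic regression
#' of case status on the chapter flag, stratified on the matched sets, and
#' reports the within-stratum odds ratio with a Wald confidence interval.
#' Chapters with no discordant stratum are reported as inestimable; complete
#' separation is flagged and the OR reported as unbounded.
#'
#' @param strata Long matched-strata tibble from [match_controls()]
#'   (`stratum`, `person_id`, `role`).
#' @param chapter_flags Wide flag tibble from [pool_who_chapters()], keyed by
#'   `person_id`. Members without flags (index year excluded) drop their
#'   whole stratum.
#' @param conf_level Confidence level; default 0.95.
#'
#' @return A `chapter_contrast` tibble: `chapter`, `log_or`, `se`,
#'   `odds_ratio`, `conf_low`, `conf_high`, `n_discordant_strata`, `status`
#'   (`"ok"`, `"inestimable"`, `"unbounded"`).
#' @export
chapter_contrast <- function(strata, chapter_flags, conf_level = 0.95) {
  check_columns(strata, c("stratum", "person_id", "role"), "strata")
  dat <- dplyr::inner_join(
    dplyr::select(strata, "stratum", "person_id", "role"),
    chapter_flags,
    by = "person_id"
  )
  complete <- dat |>
    dplyr::count(.data$stratum) |>
    dplyr::filter(.data$n == 3)
  dat <- dplyr::semi_join(dat, complete, by = "stratum") |>
    dplyr::mutate(is_case = as.integer(.data$role == "case"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(1:22, function(ch) {
    col <- sprintf("ch%02d", ch)
    d <- tibble::tibble(
      stratum = dat$stratum, is_case = dat$is_case, exposed = dat[[col]]
    )
    disc <- d |>
      dplyr::group_by(.data$stratum) |>
      dplyr::summarise(disc = dplyr::n_distinct(.data$exposed) > 1, .groups = "drop")
    n_disc <- sum(disc$disc)
    if (n_disc == 0) {
      return(tibble::tibble(
        chapter = ch, log_or = NA_real_, se = NA_real_, odds_ratio = NA_real_,
        conf_low = NA_real_, conf_high = NA_real_,
        n_discordant_strata = 0L, status = "inestimable"
      ))
    }
    fit <- suppressWarnings(
      survival::clogit(is_case ~ exposed + strata(stratum), data = d)
    )
    b <- unname(coef(fit)[1])
    se <- sqrt(vcov(fit)[1, 1])
    status <- if (!is.finite(b) || abs(b) > 10 || se > 100) "unbounded" else "ok"
    tibble::tibble(
      chapter = ch, log_or = b, se = se, odds_ratio = exp(b),
      conf_low = exp(b - z * se), conf_high = exp(b + z * se),
      n_discordant_strata = as.integer(n_disc), status = status
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("chapter_contrast", class(out))
  out
}

#' @rdname chapter_contrast
#' @param x A `chapter_contrast`.
#' @param ... Unused.
#' @export
tidy.chapter_contrast <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::transmute(
      term = sprintf("ch%02d", .data$chapter),
      estimate = .data$log_or,
      std_error = .data$se,
      odds_ratio = .data$odds_ratio,
      conf_low = .data$conf_low,
      conf_high = .data$conf_high,
      status = .data$status
    )
}

#' Run the full matched-cohort analysis on a synthetic registry
#'
#' Wires the pipeline end to end: qualifying index years, 1:2 exact-key
#' matching, WHO-chapter pooling with the stratum case's index year applied
#' to controls, and per-chapter conditional-logistic contrasts.
#'
#' @param registry A `synthetic_registry` from [generate_registry()].
#' @param case_codes Qualifying codes; default [default_case_codes()].
#' @param seed Run seed for control sampling.
#' @param age_band Age matching half-width (whole years); default 0.
#'
#' @return List with `index`, `strata`, `chapter_flags`, and `contrast`
#'   (a [chapter_contrast()] tibble).
#' @export
cohort_analysis <- function(registry, case_codes = default_case_codes(),
                            seed = 1L, age_band = 0L) {
  if (!inherits(registry, "synthetic_registry")) {
    stop_invalid("registry", "must be a synthetic_registry")
  }
  index <- assign_index_dates(registry$diagnoses, case_codes,
                              registry$spec$year_range)
  cases <- registry$persons |>
    dplyr::filter(.data$is_case) |>
    dplyr::select("person_id", "birth_year", "gender",
                  "married_coliving", "municipality") |>
    dplyr::inner_join(dplyr::select(index, "person_id", "index_year"),
                      by = "person_id")
  pool <- registry$persons |>
    dplyr::filter(!.data$is_case) |>
    dplyr::select("person_id", "birth_year", "gender",
                  "married_coliving", "municipality")
  strata <- match_controls(cases, pool, seed = seed, age_band = age_band)
  # controls inherit the stratum case's index year for the comorbidity window
  member_index <- dplyr::select(strata, "person_id", "index_year")
  flags <- pool_who_chapters(registry$diagnoses, member_index)
  contrast <- chapter_contrast(strata, flags)
  list(index = index, strata = strata, chapter_flags = flags,
       contrast = contrast)
}
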