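# Independent oracles used to cross-check the implementation.

# Conditional-logistic MLE for matched sets with one case and any number of
# controls and a scalar exposure, by direct maximization of the conditional
# likelihood: the case's exposure against the stratum's exposure set,
#   L(b) = prod_s exp(b x_case) / sum_j exp(b x_j).
# Deliberately independent of survival::clogit.
oracle_clogit <- function(stratum, is_case, exposed, interval = c(-8, 8)) {
  strata_split <- split(data.frame(is_case, exposed), stratum)
  negloglik <- function(b) {
    -sum(vapply(strata_split, function(s) {
      num <- b * s$exposed[s$is_case == 1]
      num - log(sum(exp(b * s$exposed)))
    }, numeric(1)))
  }
  stats::optimize(negloglik, interval)$minimum
}

# Adjusted Rand index between two labelings (closed form on the pair
# contingency table); used to score recovery of planted cluster structure.
ari <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

# TRUE when two labelings induce the same partition (equal up to relabeling).
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Population (1/n) standard deviation, restated independently of the package.
pop_sd_acc <- function(x) sqrt(mean((x - mean(x))^2))

# A tiny deterministic patient table for formula-level tests.
toy_patients <- function(n = 6) {
  tibble::tibble(
    patient_id = sprintf("T%02d", seq_len(n)),
    department_id = rep(c("DA", "DB"), length.out = n),
    age = seq(30, 30 + 10 * (n - 1), by = 10) / 1,
    gender = rep(c("female", "male"), length.out = n),
    obesity = rep(c(0, 1), length.out = n),
    smoking = rep(c(1, 0), length.out = n),
    n_comorbidities = rep(0:2, length.out = n),
    pasi_before = seq(8, 8 + 2 * (n - 1), by = 2),
    pasi_actual = seq(6, 6 + 2 * (n - 1), by = 2),
    goal_1_actual = seq(3, 3 + n - 1),
    goal_2_actual = rev(seq(3, 3 + n - 1)),
    weight_1 = 0.5,
    weight_2 = 0.5
  )
}
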