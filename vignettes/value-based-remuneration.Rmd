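---
title: "Value-based remuneration for psoriasis care: models, pipelines, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value-based remuneration for psoriasis care: models, pipelines, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(outcomepay)
library(dplyr)
```

# The problem

Psoriasis (PsO) and psoriatic arthritis (PsA) care is conventionally paid by
activity: departments are reimbursed per contact and procedure, regardless of
whether patients end up better. `outcomepay` implements and stress-tests a
value-based alternative in which a hospital department is paid from a fixed
budget pool in proportion to the *better-than-anticipated* outcomes it creates
for its patients, where "outcome" spans both the clinician-scored PASI
(Psoriasis Area and Severity Index, range 0–72, lower is better) and the
outcome goals patients themselves prioritise.

The package covers four connected workflows:

1. **Payment models** — two patient-level remuneration formulas built on an
   anticipated-PASI prediction, with a budget-calibrated scaling factor.
2. **Incentive simulation** — a Monte-Carlo harness probing budget compliance,
   effort monotonicity, and the scheme's known collusion "side effect".
3. **Matched-cohort registry pipeline** — 1:2 exact-key matching, cost/income
   eligibility and censoring rules, WHO-chapter comorbidity pooling, and
   conditional-logistic case-control contrasts.
4. **Concept mapping** — card-sort co-occurrence, nonmetric MDS, Ward
   clustering, and importance-rating summaries, the method used to elicit
   which disease aspects matter to patients.

Because the person-level registries such analyses normally run on are not
publicly available, every workflow is paired with a seeded synthetic-data
generator that plants known structure, so all claims in this vignette are
backed by parameter-recovery tests rather than by inaccessible data.

# The payment models

## Anticipated PASI

Both models start from a linear prediction of the PASI a patient is expected
to reach after treatment:

$$PS_{p,\mathrm{Exp}} = \beta_0 + \beta_1 PS_{p,\mathrm{Bef}}
  + \beta_2 KR_p + \beta_3 KM_p + \beta_4 BG_p$$

with $PS_\mathrm{Bef}$ the pre-treatment PASI, $KR$ the obesity/smoking
lifestyle count, $KM$ the comorbidity count, and $BG$ background covariates.
Two conventions had to be fixed here because the model statement leaves them
open:

* **Encoding.** $KR$ is the count of obesity and smoking flags (0–2), $KM$ the
  comorbidity count, and $BG$ a two-slot vector (age in decades, male
  indicator) with its own coefficient per slot. Whether $BG$ is a scalar or a
  vector is a convention, not a substantive claim; the encoding is documented
  on `prediction_coefficients()` and tested.
* **No clipping.** The linear predictor is *not* clipped to the PASI range
  [0, 72]. The payment formulas consume differences $PS_\mathrm{Exp} -
  PS_\mathrm{Act}$, and clipping would silently distort those differences for
  severe or very mild patients.

In deployment the coefficients come from literature estimates;
`fit_coefficients()` provides the least-squares fitting path needed to verify
parameter recovery on synthetic data (slopes recovered within ±0.05 at
n = 5000 with outcome noise SD 2 in the test suite).

## Model A: PASI difference with a patient-priority correction

$$Afl_p = (PS_{p,\mathrm{Exp}} - PS_{p,\mathrm{Act}}) \cdot \alpha_p \cdot k$$

The correction factor $\alpha$ rewards treatment that served the goals the
patient weighted highly. For two goals

$$\alpha_p = \frac{O_1 w_1 + O_2 w_2}{(O_1 + O_2)/2},$$

generalized in `compute_alpha()` to $I$ goals as the weighted mean of per-goal
changes over their unweighted mean: $\alpha > 1$ exactly when highly weighted
goals improved more than average, and $\alpha = 1$ whenever weights are equal
or all goals changed equally, collapsing the payment to the pure
PASI-difference form.

Two choices worth making explicit:

* The per-goal "change" $O_i$ has no stated baseline; the package uses
  $O_i = o_{i,\mathrm{Act}} - o_{i,\mathrm{Exp}}$, the same
  actual-minus-anticipated contrast Model B uses, so both models reward the
  same notion of surprise.
* $\alpha$ is unbounded by design, and undefined (an error, not a silent 1)
  when the unweighted mean change is zero.

## Model B: weighted outcome-goal differences

Model B pays for better-than-anticipated results on the patient's own outcome
goals. Anticipated goal values come from a standardized-deviation projection:
each patient's anticipated PASI is placed within the system-wide spread,

$$\mathrm{Deviation}_p = \frac{PS_{p,\mathrm{Exp}} - \mu}
  {\sqrt{\tfrac1n \sum_p (PS_{p,\mathrm{Exp}} - \mu)^2}},$$

and the patient is assumed to deviate from the mean *actual* result of every
outcome goal by the same number of SDs:

$$o_{i,p,\mathrm{Exp}} = \mathrm{Deviation}_p \cdot
  \sqrt{\tfrac1n \sum_p (o_{i,p,\mathrm{Act}} - \mu_{o_i})^2} + \mu_{o_i}.$$

Both radicals are population ($1/n$) standard deviations, exactly as printed
in the source formulas — not the sample $1/(n-1)$ form; `pop_sd()` is used
throughout and `stats::sd()` deliberately avoided. The payment is then

$$Paym_p = \Big(\sum_{i=1}^I w_{i,p}
  (o_{i,p,\mathrm{Act}} - o_{i,p,\mathrm{Exp}})\Big) \cdot k.$$

A useful identity, tested as a property: projecting the PASI channel onto
itself returns each patient's own anticipated PASI.

## Calibrating k and the budget guarantee

The scaling factor $k$ is calibrated so that the total payout equals the
budget limit $X$ (by default 2% of the department budget, the replacement for
a discontinued across-the-board productivity requirement):

$$k = \frac{X}{\sum_p \max(\mathrm{value}_p, 0)}.$$

**Flooring negative values is a deliberate resolution of an under-specified
corner.** With raw negative values in the denominator the calibration can
yield a negative $k$ or payouts above $X$, contradicting the guarantee that
the amount paid out can never exceed the limit. Flooring at zero preserves the
guarantee exactly: the budget invariant (payout $\le X$, with equality
whenever any patient created positive value) holds for every population, and
is exercised over 200 randomized rounds in the acceptance suite. The worked
consequence: a department whose patients contribute 3 value units of a
system-wide 10 receives exactly 30% of $X$; a sole improver receives all of
$X$ no matter how small its improvement.

# Incentive properties

`run_round()` applies department-level effort multipliers to *realized
improvements* while holding anticipated values fixed at their baseline
(ex-ante) levels: $o_\mathrm{Act}' = o_\mathrm{Exp} + m\,(o_\mathrm{Act} -
o_\mathrm{Exp})$. Anchoring the risk adjustment before effort is observed is
the economically meaningful reading — a payer's anticipation cannot depend on
the behaviour it is meant to incentivise — and it makes the scheme's
documented side effect an exact algebraic fact rather than an approximation:
scaling every improvement by the same $c > 0$ scales every patient value by
$c$, leaves every department share unchanged (to 1e-9 in the tests), and
still pays out the full limit. Departments that uniformly lower their effort
are paid as if they had not. This is the price of hard budget compliance, and
`aspect_report()` flags it, together with per-round limit compliance and
payment monotonicity for a focal department.

# The matched-cohort pipeline

The registry pipeline reproduces the analytical rules of a national-registry
burden-of-disease study, on synthetic data:

* **Index dates**: first qualifying contact (default code list: L40.0, L40.4
  plaque/guttate PsO; L40.5, M07.0–M07.3, M45 PsA, with sub-codes matched by
  prefix); analysis windows are index ±15 years intersected with 1998–2014
  follow-up.
* **Matching**: 1:2 on exact age at index, gender, married/co-living, and
  municipality, sampled uniformly without replacement under a run seed.
  Exact matching is the simplest faithful reading of "matched (1:2)"; an
  `age_band` argument widens the age key if needed. Matching age is age at
  index (birth year is not stated as the alternative anywhere; age at index
  is the epidemiologically standard choice).
* **Cost eligibility**: the first post-index year must be survived in full;
  later periods require only being alive at period start.
* **Income censoring**: missing (not zero) for ages 0–15 and incomes above
  270,000 EUR/year; income years restricted to 1998–2013.
* **Comorbidity**: all diagnosis roles (main, action, secondary) within ±3
  years of the index year, pooled onto the 22 WHO ICD-10 chapters, which
  restricts analysable index years to 2001–2011. The "action" role has no
  universal definition outside the Danish patient register and is carried as
  a plain role label.
* **Contrasts**: per-chapter conditional logistic regression
  (`survival::clogit`) on the matched sets; chapters with no discordant
  stratum are reported as inestimable, separation as unbounded. The test
  suite cross-checks the estimates against a hand-written conditional
  likelihood maximized directly.

One structural caveat the tests respect: qualifying PsO/PsA codes live in WHO
chapters XII and XIII, so those two chapters are enriched in cases by
construction — in the synthetic recovery suite as in any real registry — and
planted-effect recovery is asserted on the other 20 chapters (within ±0.15
log-odds at 2000 cases).

# Concept mapping

`cosort_matrix()` counts, for each statement pair, the participants who piled
them together; `scale_to_plane()` embeds statements in two dimensions by
nonmetric MDS on the dissimilarity (participant count minus similarity),
initialized from the classical metric solution and therefore deterministic;
statements always piled together are collapsed to a single point first (their
dissimilarity is zero, which Kruskal's algorithm cannot digest, and their
coordinates should coincide anyway). `rating_summary()` reports per-cluster
and per-subcluster means and medians of the 1–5 importance ratings to one
decimal, as such tables are conventionally printed.

**Clustering input.** The classical concept-mapping pipeline clusters the 2-D
coordinates. At realistic sizes (40 statements, 12 participants, 7 clusters)
the planar embedding carries 20–30% stress, and Ward clustering on the plane
sometimes fragments a true cluster. `cluster_statements()` therefore accepts
either input, and `concept_map()` defaults to Ward linkage on the *full*
co-sort dissimilarity, which uses all the sorted information; the planar map
remains the display device. With that default, the planted 7-cluster
structure is recovered with adjusted Rand index above 0.8 at sorting fidelity
0.9 (and exactly at fidelity 1.0) in the tests.

**Rating direction.** The elicitation scale labels 1 as "very important" and
5 as "not important", yet published summary tables show *high* means for the
aspects described as most important, implying the reverse coding. The package
treats higher = more important throughout and leaves any re-coding to the
user; the discrepancy is inherent to the source material and cannot be
resolved from inside the data.

# The synthetic-data generators

The generators are first-class, tested code; their defaults are the study
conditions under which all recovery claims are made.

* **Population** (`generate_population()`): pre-treatment PASI from a
  truncated-at-0 normal (mean 12, SD 6, capped at 72); obesity 40%, smoking
  35%, five comorbidity flags at 30%; ages uniform 20–80; actual
  post-treatment PASI is the true linear predictor plus normal noise (default
  SD 2), clamped to [0, 72]; outcome-goal actuals are correlated with the
  patient's PASI improvement (default correlation 0.5) so the
  standardized-deviation projection has signal, which is precisely the
  assumption the projection encodes; importance weights are
  Dirichlet(1, ..., 1), hence nonnegative and summing to 1. Distributions are
  not stated by the source material; these were chosen once as simple,
  positive-valued, and easy to invert in tests.
* **Registry** (`generate_registry()`): defaults of 200 cases and 800 pool
  members followed 1998–2014, index years 2001–2011. The first 2·n_cases pool
  members copy case matching keys pairwise, guaranteeing full 1:2 matching by
  construction. Costs are log-normal with an additive case shift from the
  index year on (default 1500 EUR/year); incomes log-normal around 32,000
  EUR. Comorbid conditions are *chronic*: a present condition generates
  recurring annual contacts (probability 0.5/year, at least one), so any
  ±3-year window captures it for cases and controls alike — placing a single
  diagnosis near a person's own reference year instead makes control exposure
  window-dependent and visibly biases every chapter's odds ratio upward.
* **Sortings** (`generate_sortings()`): 40 statements, 12 participants (two
  focus groups of six), 7 planted clusters, fidelity 0.9; pile labels are
  permuted per participant since only co-membership carries information;
  ratings are normal around per-cluster means (defaults spread 2.5–4.5),
  rounded and clipped to the 1–5 integer scale.

What the generators do *not* emulate: real Danish registry marginals
(prevalence, cost levels, municipality sizes), informative dropout, coding
drift over calendar time, or semantic similarity between statements. Passing
recovery tests therefore demonstrates that the estimators recover what the
generators plant under clean conditions — not that effect sizes from real
registries would be recovered with the same precision.

# Numerical choices and degenerate inputs

* Population SDs ($1/n$) everywhere in the payment formulas; ties in Ward
  clustering resolved by `stats::hclust`'s deterministic ordering; nonmetric
  MDS initialized from `cmdscale`, hence seed-free and reproducible.
* Zero spread of anticipated PASI, zero unweighted mean outcome change, a
  system with no positive patient value, and degenerate (all-equal)
  similarity matrices raise classed errors rather than returning NaN.
* Validation failures name the offending field; unknown YAML configuration
  keys are rejected, not ignored.
* Problem sizes used by the test and acceptance suites — 5000 patients for
  coefficient recovery, 2000 cases for chapter contrasts, 200 payment rounds,
  40 × 12 sortings — were chosen as the smallest sizes at which the stated
  tolerances are comfortably identified.

# Limitations

* The coefficient-fitting path is a verification device for synthetic data;
  no clinical validity of the PASI prediction is claimed or tested.
* The incentive harness evaluates specified behaviour scenarios; it does not
  solve for equilibrium behaviour, and it quantifies the collusion incentive
  rather than its likelihood.
* Statement de-duplication in concept mapping is exact-text only.
* Multi-year budget carry-over and real DRG/DAGS tariff handling are out of
  scope.
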