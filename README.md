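# outcomepay

Value-based remuneration modelling for psoriasis (PsO) and psoriatic
arthritis (PsA) hospital care.

Activity-based hospital financing pays for contacts and procedures, not for
whether patients end up better. `outcomepay` implements a value-based
alternative for dermatology/rheumatology departments, built for health
economists and biostatisticians who want to stress-test such a scheme before
piloting it: two patient-level payment models on top of an anticipated-PASI
prediction, a budget-calibrated scaling factor with a hard payout guarantee,
a Monte-Carlo incentive harness, plus the two supporting evidence pipelines
such a scheme rests on — a matched (1:2) case-control registry workflow and a
concept-mapping workflow for eliciting patient-priority outcome goals. Seeded
synthetic-data generators stand in for the national registries such analyses
normally require, so everything here runs self-contained.

## The models in brief

Anticipated PASI after treatment (PASI: Psoriasis Area and Severity Index,
range 0–72, lower is better) is a linear prediction from pre-treatment
severity and risk factors:

    PS_Exp = β0 + β1·PS_Bef + β2·KR + β3·KM + β4·BG

**Model A** pays for a better-than-anticipated PASI, corrected by how well
treatment served the patient's own weighted outcome goals:

    Afl_p = (PS_Exp − PS_Act) · α_p · k,   α_p = Σ O_i w_i / (Σ O_i / I)

**Model B** pays directly for better-than-anticipated outcome goals, with
anticipated goal values projected from each patient's standardized deviation
within the system-wide anticipated-PASI spread:

    Paym_p = ( Σ_i w_i (o_i,Act − o_i,Exp) ) · k

In both, k is calibrated against a budget limit X (by default 2% of the
department budget) as k = X / Σ max(value_p, 0), which guarantees total
payout never exceeds X and pays X in full whenever anyone created positive
value. Department shares of X are proportional to the floored value their
patients created.

## Worked example

Generate a synthetic treated population, pay it under Model B from a 2%
budget pool, and inspect the ledger:

```r
library(outcomepay)

pop <- generate_population(population_spec(n_patients = 200,
                                           n_departments = 4, seed = 1))
config <- remuneration_config(budget_limit = budget_limit_from_department(1e6),
                              model = "B")
ledger <- remunerate(pop, config)
ledger
#> <payment_ledger> model B | 200 patients | k = 109.248 | payout 20000.00 of limit 20000.00
#> # A tibble: 200 × 5
#>   patient_id department_id  value value_floored payment
#>   <chr>      <chr>          <dbl>         <dbl>   <dbl>
#> 1 P0001      D01           -2.81              0       0
#> 2 P0002      D04           -0.168             0       0
#> 3 P0003      D03           -1.19              0       0
#> # ℹ 197 more rows

ledger_departments(ledger)
#> # A tibble: 4 × 4
#>   department_id value share payment
#>   <chr>         <dbl> <dbl>   <dbl>
#> 1 D01            53.8 0.294   5882.
#> 2 D02            54.0 0.295   5895.
#> 3 D03            37.5 0.205   4095.
#> 4 D04            37.8 0.206   4128.
```

Reading this: a 1,000,000 EUR department budget yields a value-based pool of
X = 20,000 EUR. Each patient's `value` is the weighted sum of
actual-minus-anticipated outcome-goal results; negative values (worse than
anticipated) are floored to zero at payout. The calibrated k = 109.2 converts
value units to EUR so the pool is paid out exactly; departments D01–D04 split
X in proportion to the value their patients created (29.4%, 29.5%, 20.5%,
20.6%).

The other workflows follow the same shape — generate, analyse, summarise:

```r
reg <- generate_registry(registry_spec(seed = 1))   # 200 cases, 800 pool
res <- cohort_analysis(reg)                         # match, pool, contrast
res$contrast                                        # per-WHO-chapter odds ratios

srt <- generate_sortings(sorting_spec(seed = 1))    # 12 participants, 40 statements
cm  <- concept_map(srt$sortings, srt$ratings, n_clusters = 7)
autoplot(cm)                                        # MDS map coloured by cluster
```

A command-line wrapper over the same functions ships in
`inst/scripts/outcomepay` (subcommands `generate`, `remunerate`, `simulate`,
`cohort`, `conceptmap`; YAML config with strict key validation, CSV/JSON
outputs and a run manifest).

See `vignettes/value-based-remuneration.Rmd` for the full account of the
models, the generators' assumptions, and the design decisions.

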