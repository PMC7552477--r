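# Example run configuration for the outcomepay command-line wrapper.
# Unknown keys anywhere in this file are rejected, not ignored.
seed: 1
synthetic:
  population:
    n_patients: 200
    n_departments: 4
    n_outcome_goals: 2
  registry:
    n_cases: 200
    n_pool: 800
  sorting:
    n_statements: 40
    n_participants: 12
    n_true_clusters: 7
    sort_fidelity: 0.9
coefficients:
  beta0: 1.0
  beta1: 0.55
  beta2: 1.0
  beta3: 0.5
  beta4_age_decades: 0.15
  beta4_gender_male: 0.3
remuneration:
  budget_limit: 20000   # e.g. 2% of a 1,000,000 EUR department budget
  productivity_rate: 0.02
  k: auto
  model: B
simulation:
  rounds: 200
conceptmap:
  n_clusters: 7
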