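# Base-case configuration: the published model inputs.
# Unit costs are placeholders (the source prints none); everything else is
# the published figure.
risk_summary:
  incidence: 0.1676
  factors:
    - {name: bmi, kind: continuous, odds_ratio: 1.95, value: 26.41}
    - {name: colostomy, kind: binary, odds_ratio: 2.03, value: 0.53}
    - {name: terminal, kind: binary, odds_ratio: 1.46, value: 0.51}
    - {name: parastomal_hernia, kind: binary, odds_ratio: 3.42, value: 0.11}
  n_patients: 2455
mesh_summary:
  incidence: 0.1238
  odds_ratio: 0.21
  proportion: 0.34
  n_patients: 2008
p_pooled_no_mesh: 0.1939
variant: as_published
high_risk_fraction: 0.5
risk_threshold: 0.2280
wtp: 58000000
n_patients: 100000
n_psa: 10000
seed: 1
costs:
  closure: 10000000
  closure_with_mesh: 10900000
  hernia_repair: 3000000
  consults: 250000
uncertainty:
  n_eff_risk: 2455
  n_eff_mesh: 2008
  cost_cv: 0.2
  prob_dist: beta
  cost_dist: gamma
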