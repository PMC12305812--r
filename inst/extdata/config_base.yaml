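seed: 20260901
cohort:
  n_base: 1707.0
  expand_n: 100000
  p_age_band:
  - 0.274751025190393
  - 0.348564733450498
  - 0.37668424135911
  p_sex:
  - 0.510837727006444
  - 0.489162272993556
  p_wealth:
  - 0.175161101347393
  - 0.189220855301699
  - 0.215582893966022
  - 0.236086701816052
  - 0.183948447568834
  p_anaemia_state:
  - 0.413005272407733
  - 0.240187463386057
  - 0.33626244874048
  - 0.010544815465729
  hb_mean_by_state:
    none: 12.4
    mild: 10.5
    moderate: 8.5
    severe: 6.2
  hb_sd_by_state:
    none: 1.0
    mild: 0.5
    moderate: 0.8
    severe: 0.6
  p_ifc_by_sex:
    boy: 0.056
    girl: 0.043
markov:
  n_cycles: 20
  cycle_days: 182.5
  mode: cohort_fractions
  worsening_rates:
    none_mild: 0.1
    mild_moderate: 0.06
    moderate_severe: 0.01
  recovery_pattern:
    mild_none: 1.0
    moderate_mild: 0.7
    severe_moderate: 0.7
  calibration:
    non_ifc:
      start_prev: 0.57
      end_prev: 0.36
    ifc:
      start_prev: 0.59
      end_prev: 0.27
    anaemic_shares:
    - 0.409181636726547
    - 0.572854291417166
    - 0.017964071856287
    tol_multiplier: 1.0e-06
    tol_prevalence: 0.0001
daly:
  disability_weights:
    none: 0.0
    mild: 0.004
    moderate: 0.052
    severe: 0.149
  discount:
    annual_rate: 0.03
    grace_years: 1.0
costs:
  home_food_per_day: 0.37
  ifc_increment_per_day: 0.17
  intervention_months: 18.0
  days_per_month: 30.0
wtp:
  gdp_per_capita_per_day: 6.6
  multiplier: 1.0
psa:
  n_runs: 1000
  rel_ci_halfwidth: 0.2
oneway:
  rel_bound: 0.2
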