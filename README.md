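# ifcsim

Markov microsimulation and cost-effectiveness analysis of iron-fortified
infant cereals (IFC) against iron-deficiency anaemia in young children.

## The problem

Anaemia in children under two is common in Egypt and much of the Eastern
Mediterranean, and iron deficiency is its leading cause. Fortified infant
cereals are a cheap, high-compliance intervention, but the policy question
is economic: does adding ~0.17 USD/day of fortified cereal to a child's
diet for up to 18 months buy enough health, over a 10-year horizon, to be
worth funding? `ifcsim` is for health economists and nutrition-policy
analysts who want that question answered with a transparent, fully
reproducible simulation rather than a spreadsheet.

## The model

- **Cohort.** A synthetic survey-like base sample of 1,707 children
  (age band, sex, wealth quintile, haemoglobin, anaemia severity, IFC
  flag), expanded by Monte-Carlo resampling to a 100,000-child virtual
  cohort. Severity follows the WHO haemoglobin cut-offs
  (severe < 7, moderate [7, 10), mild [10, 11), none ≥ 11 g/dL).
- **Markov projection.** Four severity states over 20 six-month cycles.
  Per-cycle matrices are built from worsening/recovery rates by the
  competing-risks conversion *p* = 1 − e^(−rate), restricted to
  adjacent-state moves. The non-IFC arm is calibrated (bisection on a
  recovery-rate multiplier) to fall from 57% to 36% anaemia prevalence over
  10 years; the IFC arm applies a relative risk *rr* to the worsening
  rates, calibrated to reach 27% (default *rr* ≈ 0.67).
- **Burden.** DALYs as years lived with disability:
  Σₜ occupancyₜ·weight × 182.5 days, GBD-2019 anaemia weights
  (0.004/0.052/0.149), 3% annual discounting after year 1.
- **Decision.** ICER = ΔCost/ΔEffect with cost-effectiveness-plane
  quadrant, WHO-CHOICE classification against a 6.6 USD/day GDP-per-capita
  threshold, net monetary benefit, and population-level savings.
- **Uncertainty.** One-way (tornado) analysis and probabilistic
  sensitivity analysis (gamma costs, beta weights/risks, method-of-moments
  fits from 95% CIs) with cost-effectiveness acceptability curves.

See `vignettes/ifc-cea-methods.Rmd` for assumptions, calibration details
and limitations.

## Worked example

```r
library(ifcsim)

# headline arithmetic on the reference per-child inputs
r <- icer(291, 199.8, 77, 99)   # costs (USD); disability days per arm
r$icer                          # -4.145455
r$quadrant                      # "more costly, more effective"
classify_who_choice(r$icer)     # "highly cost-effective"
population_savings(1.92, 4058000)$millions  # 7.79 (million USD)

# the full simulated pipeline
cfg <- default_run_config(expand_n = 100000, seed = 2026)
res <- run_cea(cfg, out_dir = "ifcsim_out")
res$result
#> Cost-effectiveness result (10-year horizon)
#>   cost/child:        IFC 291.60 USD vs non-IFC 199.80 USD (delta 91.80)
#>   disability days:   IFC 29.3 vs non-IFC 35.1 (averted 5.9)
#>   DALY/day:          IFC 0.0080 vs non-IFC 0.0096 (averted 0.0016)
#>   ICER:              -15.674 USD per disability day averted (more costly, more effective)
#>   classification:    cost-effective
#>   NMB at threshold:  -53.14 USD
```

The first block reproduces the reference cost-effectiveness arithmetic: a
negative ICER of −4.15 USD per disability day averted whose magnitude is
well under the 6.6 USD willingness-to-pay benchmark. The second block runs
the package's own calibrated projection; its per-arm disability days are
lower than the reference totals (no transition estimates exist to anchor
the absolute level), but the qualitative conclusion — extra cost, meaningfully less
disability, ICER magnitude under 3× the benchmark — is the same.

Other entry points: `run_simulate()` (cohort + trajectories + burden),
`run_oneway()` (tornado), `run_psa_analysis()` (PSA + CEAC), all driven by
a YAML config (`write_run_config()` / `read_run_config()`), plus a
command-line wrapper at `inst/cli/ifcsim.R` with `simulate`, `cea`,
`oneway`, `psa` and `report` subcommands. Ready-made scenario configs
(base case, 10% and 20% IFC-cost reductions) ship in `inst/extdata/`.

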