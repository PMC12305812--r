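---
title: "Modelling the cost-effectiveness of iron-fortified infant cereals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of iron-fortified infant cereals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ifcsim evaluates whether adding iron-fortified infant cereals (IFC) to the
diet of children aged 6–24 months is a cost-effective way to reduce
iron-deficiency anaemia, using Egypt as the study setting. The pipeline has
five stages: a synthetic survey-like cohort, a Markov anaemia-severity
projection for an IFC and a non-IFC arm, disability (DALY) accounting,
incremental cost-effectiveness evaluation, and sensitivity analysis. This
vignette explains the model, its assumptions, and the design decisions a
user should understand before trusting (or overriding) the defaults.

```{r setup}
library(ifcsim)
```

## The synthetic cohort

No child-level microdata from the underlying national survey are
redistributable, so the package generates a cohort with the same marginal
structure: 1,707 children aged 6 to <24 months with age band, sex,
wealth-index quintile, haemoglobin (Hb), anaemia severity and an IFC
consumption flag (5.6% of boys, 4.3% of girls). Severity follows the WHO
cut-offs, with lower-closed half-open intervals: severe Hb < 7 g/dL,
moderate [7, 10), mild [10, 11), none ≥ 11.

Fields are sampled independently of one another. This is a deliberate
simplification: the survey summary reports no significant association
between anaemia severity and sex, age band or wealth (all p > 0.13), and no
joint table is available to calibrate against. The one dependency that is
enforced is Hb given severity: Hb is drawn from a normal truncated to the
severity interval, so `categorize_anaemia(hb)` always agrees with the
stored state. Per-state means default to 12.4/10.5/8.5/6.2 g/dL (SD
1.0/0.5/0.8/0.6). Interval midpoints would be a simpler rule, but the
open-ended healthy interval (midpoint 18 g/dL) and the severe interval
(midpoint 3.5 g/dL) are clinically implausible; the chosen means reproduce
the reported overall mean of about 10.6 g/dL as a mixture. The overall SD
of the synthetic cohort (≈1.9 g/dL) is somewhat above the reported 1.6,
because state masses are fixed by the severity marginals; we treat the
overall mean ± SD as a soft diagnostic, not a constraint.

The base cohort is expanded to a virtual cohort (default 100,000 children)
by resampling records with replacement and reassigning ids. Every marginal
of the expansion converges to the base frequency at the multinomial rate
`sqrt(p(1-p)/n)`; the test suite asserts recovery within 3 standard errors.

What the generator does *not* emulate: survey weights, household
clustering, urban/rural geography (reported non-significant), seasonality
of Hb measurement, and any real correlation between wealth and IFC access.
Tests passing on this cohort therefore validate the *engine*, not the
epidemiology of any particular population.

## The Markov projection

Four severity states (none < mild < moderate < severe) evolve over 20
six-month cycles (10 years, 182.5 days per cycle). Transitions are
restricted to adjacent severity levels per cycle — the conservative reading
of a model in which children shift between neighbouring anaemia grades at
6-month intervals; a full 4×4 matrix read with `read_transition_csv()` can
be supplied instead. Rates convert to probabilities by the
competing-risks rule: a state with exits at total rate *R* retains
probability `exp(-R)` and splits `1 - exp(-R)` across exits in proportion
to their rates. This keeps every row stochastic for any non-negative rates,
which matters during calibration when the search brackets are wide.

No longitudinal transition estimates exist for this population; only
baseline and projected 10-year prevalences are reported, so the package
calibrates:

1. **Non-IFC arm.** Worsening rates per cycle are fixed (defaults 0.10,
   0.06, 0.01 for none→mild, mild→moderate, moderate→severe — values chosen
   to give plausible incidence of new anaemia over six months) and a single
   scalar multiplier on the recovery-rate pattern (1.0, 0.7, 0.7) is found
   by bisection so the projected prevalence falls from 57% to 36% over 20
   cycles. End prevalence is strictly decreasing in the multiplier, so the
   bisection is well-posed; tolerance is 1e-6 on the multiplier and the
   achieved prevalence must sit within 1e-4 of the target.
2. **IFC arm.** A relative risk `rr` multiplying the *worsening* rates
   (probability → rate → scale → probability, diagonal renormalised) is
   bisected so the IFC arm falls from 59% to 27%. The default calibration
   yields `rr ≈ 0.67`, i.e. roughly a one-third reduction in the rate of
   worsening — inside the range fortification trials report.

The IFC effect is applied as a time-homogeneous matrix over the whole
horizon even though consumption stops at age two: the model projects a
persistent effect of the early-life intervention, and exposure duration enters through costs, not transitions.

When the projection starts from a simulated cohort, both arms use the
*pooled* empirical state fractions as their common baseline (≈58%
anaemic). The IFC flag is generated independently of severity, so the
per-arm empirical baselines differ only by the binomial sampling noise of
the small IFC subgroup (~5% of the cohort); starting each arm from its own
noisy baseline would let that noise — comparable in size to the
first-cycle treatment effect — dominate the incremental disability days
and make the ICER a function of the seed rather than of the model. The
reported anchors (59% IFC vs 57% non-IFC) are asymmetric in the other
direction, and a trajectory started at 59% under the IFC matrix only
crosses below the non-IFC curve at the second cycle; the cycle-wise
dominance property — IFC prevalence ≤ non-IFC prevalence at every
timepoint — is likewise a common-baseline statement, and that is how the
package asserts it.

Two projection modes exist. `cohort_fractions` is the deterministic
product `init %*% m^t`; `individual_microsim` samples each child's path and
agrees with the deterministic mode within binomial Monte-Carlo error
(asserted at 3 SEs per state per cycle at n = 100,000). The deterministic
mode is the default everywhere speed or exactness matters (calibration,
one-way SA, PSA).

## Disability accounting

DALYs here are years lived with disability only: no anaemia mortality
rates are available for this age group, so years of life lost are structurally zero. Each
cycle contributes `occupancy · weight × 182.5` disability days, with
GBD-2019 anaemia weights as defaults (mild 0.004, moderate 0.052, severe
0.149 — taken from the GBD study itself and freely overridable).
Discounting is annual at 3%, applied after a one-year grace period:
cycle *t* belongs to year `ceiling(t/2)` and is scaled by
`1.03^-(year - 1)`. The headline incremental arithmetic uses undiscounted
days (the reference per-arm totals only reconcile undiscounted); discounted
totals are always reported alongside. "DALY per day" is total undiscounted
days divided by the 3,650-day horizon.

## Costs, ICER and decision rules

Home foods cost 0.37 USD/child/day; IFC adds 0.17 USD/day. Totals cover
the 18-month feeding window (540 days at 30 days/month): 199.8 USD without
IFC, 291.6 USD with (children starting later can be given 12- or 6-month
windows). Costs are not discounted: all food spending falls in years 1–2,
mostly inside the grace period, and the reference totals are undiscounted.
The ICER divides incremental cost by incremental effect; with disability
days as the effect unit the base case is negative ("more costly, more
effective" quadrant — more spending, less disability), and the
cost-effectiveness-plane quadrant is always reported so this case is never
confused with dominance. Classification follows WHO-CHOICE against a
willingness-to-pay benchmark of 6.6 USD/day (Egypt's daily GDP per capita):
|ICER| under 1× is highly cost-effective, under 3× cost-effective. The
absolute value is used deliberately, matching the convention of
interpreting a same-sign-ambiguous negative ICER by magnitude; net monetary
benefit (`wtp·ΔE − ΔC`) is provided for the unambiguous decision rule.

A reported constant of 1.92 USD per disability day saved feeds the
population-savings figure (1.92 × 4.058 million children ≈ 7.79 million
USD). That constant is *not* derivable from the other reported inputs
(91.2/22 ≈ 4.15), so the package treats it as an input, never recomputes
it.

## Sensitivity analysis

**One-way.** Each parameter moves to its lower and upper bound with the
rest at base; default bounds are ±20% (relative), mirroring the
cost-reduction scenarios of interest. The tornado table reports the ICER at
each bound and the swing `|high − low|`. Two structural facts are worth
knowing: the home-food cost is common to both arms and so can never move
the ICER, and among cost parameters the IFC increment consequently
dominates.

**Probabilistic.** Costs get gamma distributions, everything else beta,
parameterised by method of moments from a mean and 95% CI with
`SD = (hi − lo)/3.92` (normal-quantile width). Defaults put ±20% CIs on the
two costs, the three disability weights and the calibrated IFC relative
risk. Each of the (default 1,000) runs draws all non-fixed parameters,
rebuilds the matrices and re-runs the *deterministic* projection, so PSA
spread reflects parameter uncertainty rather than microsimulation noise;
per-child PSA is available by switching the projection mode but costs ~10^5
times more work for no inferential gain at this cohort size. Failed draws
are recorded with their reason and excluded from summaries. The CEAC
reports, at each willingness-to-pay, the fraction of runs with non-negative
net monetary benefit.

The reported PSA scenario values (median ICERs under 10%/20% IFC-cost
reductions, the 80%/40% acceptability points) depend on distribution
hyperparameters that are not reported; the package reproduces the
*machinery* and treats those figures as qualitative templates only.

## Numerical choices and degenerate inputs

- Probability vectors must sum to 1 within 1e-12 (specs) or 1e-9
  (matrices/occupancies); violations are errors, never silently
  renormalised.
- Bisection: 1e-6 on the search variable, 1e-4 on achieved prevalence;
  an unreachable target reports the bracket endpoints instead of returning
  the nearest value.
- A zero-worsening, equal-start calibration accepts a zero recovery rate.
- `probability_to_rate(1)` is an error (infinite rate), as is an ICER with
  equal effects (the error message points to net monetary benefit).
- Truncated-normal draws use the inverse-CDF method and are clamped a hair
  inside the interval so boundary Hb values can never flip severity.
- Every random operation takes an explicit integer seed; derived seeds are
  small offsets of the config seed, and reruns are byte-identical.

## Problem sizes

The package's own checks run the base cohort at 1,707, the virtual cohort
at 100,000 for the marginal-recovery and microsimulation-agreement
assertions and at 2,000–5,000 for pipeline plumbing tests, the PSA at
200–1,000 runs, and distribution-fit Monte-Carlo checks at 10^5 draws.

## Limitations

The cohort is synthetic: results demonstrate the method, not new evidence
about any real population. Anaemia aetiology is collapsed to a single
severity chain — no iron-status biology, no other micronutrient
deficiencies, no mortality, no age-varying transitions after the exposure
window. Costs cover food only; healthcare utilisation and productivity are
out of scope. The calibration absorbs all structural uncertainty about the
true transition process into two scalars, so alternative worsening-rate
patterns reaching the same endpoints are observationally equivalent to the
default — users with longitudinal data should fit matrices directly and
pass them in.
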