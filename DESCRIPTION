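Package: ifcsim
Title: Cost-Effectiveness Microsimulation of Iron-Fortified Infant
    Cereals Against Childhood Anaemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov state-transition microsimulation and cost-effectiveness
    analysis of iron-fortified infant cereals (IFC) for iron-deficiency
    anaemia in young children. Generates a synthetic survey-like cohort
    stratified by age band, sex, wealth quintile, haemoglobin and anaemia
    severity; expands it by Monte Carlo resampling into a virtual cohort;
    projects anaemia severity over six-month cycles for IFC and non-IFC
    arms; converts state occupancy into disability-adjusted life years
    (years lived with disability, with annual discounting); and evaluates
    incremental cost-effectiveness ratios against willingness-to-pay
    thresholds, with one-way (tornado) and probabilistic sensitivity
    analysis and cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
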