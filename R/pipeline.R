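#' Assemble the calibrated model setup from a configuration
#'
#' Performs the two calibration steps of the base case — solve for the
#' recovery-rate multiplier that takes the non-IFC arm from its baseline
#' prevalence to its 10-year target, then for the relative risk on
#' worsening rates that takes the IFC arm to its own target — and bundles
#' the results with baseline occupancies and all downstream parameters
#' into the object consumed by [evaluate_scenario()], [one_way_sa()] and
#' [run_psa()].
#'
#' @param cfg An `ifc_run_config` (default [default_run_config()]).
#' @param cohort Optional `ifc_cohort`; if supplied, both arms start from
#'   the cohort's pooled empirical state fractions instead of the config's
#'   calibration anchor prevalences. A common baseline is used because the
#'   IFC flag is generated independently of severity, so per-arm baselines
#'   differ only by the sampling noise of the small IFC subgroup — noise
#'   that would otherwise leak into every incremental result.
#' @return List of class `ifc_model_setup` with the calibrated matrices
#'   (`m_non_ifc`, `m_ifc`), `rr_ifc`, `recovery_multiplier`, baseline
#'   occupancies, the trajectory spec and the base parameter list.
#' @export
model_setup <- function(cfg = default_run_config(), cohort = NULL) {
  validate_run_config(cfg)
  mk <- cfg$markov
  cal <- mk$calibration
  spec <- trajectory_spec(mk$n_cycles, mk$cycle_days)
  cal_non <- calibrate_transitions(
    start_prev = cal$non_ifc$start_prev, end_prev = cal$non_ifc$end_prev,
    n_cycles = mk$n_cycles,
    worsening_rates = as.numeric(mk$worsening_rates),
    recovery_pattern = as.numeric(mk$recovery_pattern),
    anaemic_shares = cal$anaemic_shares, arm = "non-IFC",
    tol_multiplier = cal$tol_multiplier, tol_prevalence = cal$tol_prevalence)
  cal_ifc <- calibrate_relative_risk(
    cal_non$matrix, start_prev = cal$ifc$start_prev,
    end_prev = cal$ifc$end_prev, n_cycles = mk$n_cycles,
    anaemic_shares = cal$anaemic_shares,
    tol_rr = cal$tol_multiplier, tol_prevalence = cal$tol_prevalence)
  if (!is.null(cohort)) {
    init_ifc <- init_non <- state_occupancy(cohort)
  } else {
    init_ifc <- cal_ifc$init
    init_non <- cal_non$init
  }
  w <- cfg$daly$disability_weights
  structure(list(
    m_non_ifc = cal_non$matrix,
    m_ifc = cal_ifc$matrix,
    recovery_multiplier = cal_non$multiplier,
    rr_ifc = cal_ifc$rr,
    worsening_rates = as.numeric(mk$worsening_rates),
    recovery_pattern = as.numeric(mk$recovery_pattern),
    init_ifc = init_ifc,
    init_non_ifc = init_non,
    spec = spec,
    grace_years = cfg$daly$discount$grace_years,
    intervention_months = cfg$costs$intervention_months,
    days_per_month = cfg$costs$days_per_month,
    wtp = wtp_threshold(cfg$wtp$gdp_per_capita_per_day, cfg$wtp$multiplier),
    base_params = list(
      home_food_per_day = cfg$costs$home_food_per_day,
      ifc_increment_per_day = cfg$costs$ifc_increment_per_day,
      rr_ifc = cal_ifc$rr,
      recovery_multiplier = cal_non$multiplier,
      dw_mild = w[["mild"]], dw_moderate = w[["moderate"]],
      dw_severe = w[["severe"]],
      discount_rate = cfg$daly$discount$annual_rate)),
    class = "ifc_model_setup")
}

write_with_header <- function(df, path, cfg, extra = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# config_digest: %s", config_digest(cfg)),
               sprintf("# seed: %d", cfg$seed),
               extra), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

trajectory_df <- function(traj) {
  occ <- unclass(traj)
  data.frame(cycle = seq_len(nrow(occ)),
             arm = attr(traj, "arm"),
             none = occ[, 1], mild = occ[, 2],
             moderate = occ[, 3], severe = occ[, 4],
             prevalence = 1 - occ[, 1])
}

#' Run the simulation stage of the pipeline
#'
#' Generates the base cohort, expands it to the virtual cohort, calibrates
#' the transition matrices, projects both arms (deterministic
#' cohort-fraction projection by default, per-child microsimulation if the
#' config's `markov.mode` is `"individual_microsim"`), accumulates the
#' burden per arm and writes cohort, trajectory and burden CSVs to
#' `out_dir`. Every output carries the config digest and seed in header
#' comments, so a rerun with the same config is byte-identical.
#'
#' @param cfg An `ifc_run_config`.
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress progress messages (written to `stderr`).
#' @return Invisibly, a list with the cohort, setup, trajectories, burdens
#'   and the paths written.
#' @export
run_simulate <- function(cfg = default_run_config(), out_dir = ".",
                         quiet = FALSE) {
  validate_run_config(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  say("seed %d, config digest %s", cfg$seed, config_digest(cfg))
  pspec <- population_spec_from_config(cfg)
  base <- sample_base_cohort(pspec, seed = cfg$seed)
  cohort <- expand_cohort(base, n = cfg$cohort$expand_n, seed = cfg$seed + 1L)
  say("cohort: base %d expanded to %d", nrow(base), nrow(cohort))
  setup <- model_setup(cfg, cohort = cohort)
  say("calibrated: recovery multiplier %.4f, IFC relative risk %.4f",
      setup$recovery_multiplier, setup$rr_ifc)
  if (identical(cfg$markov$mode, "individual_microsim")) {
    trajs <- simulate_individuals(cohort,
                                  list(ifc = setup$m_ifc,
                                       non_ifc = setup$m_non_ifc),
                                  setup$spec, seed = cfg$seed + 2L)
    traj_ifc <- trajs$ifc; traj_non <- trajs$non_ifc
  } else {
    traj_ifc <- simulate_cohort_fractions(setup$init_ifc, setup$m_ifc,
                                          setup$spec)
    traj_non <- simulate_cohort_fractions(setup$init_non_ifc,
                                          setup$m_non_ifc, setup$spec)
  }
  w <- cfg$daly$disability_weights
  dw <- disability_weights(w[["mild"]], w[["moderate"]], w[["severe"]])
  d <- discount_spec(cfg$daly$discount$annual_rate,
                     cfg$daly$discount$grace_years)
  b_ifc <- disability_days(traj_ifc, dw, setup$spec, d)
  b_non <- disability_days(traj_non, dw, setup$spec, d)
  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    trajectory = file.path(out_dir, "trajectory.csv"),
    burden = file.path(out_dir, "burden.csv"),
    matrix_non_ifc = file.path(out_dir, "transition_non_ifc.csv"),
    matrix_ifc = file.path(out_dir, "transition_ifc.csv"))
  write_cohort_csv(cohort, paths$cohort)
  write_with_header(rbind(trajectory_df(traj_ifc), trajectory_df(traj_non)),
                    paths$trajectory, cfg)
  write_with_header(
    data.frame(arm = c(b_ifc$arm, b_non$arm),
               daily_daly = c(b_ifc$daily_daly, b_non$daily_daly),
               days_10y = c(b_ifc$disability_days, b_non$disability_days),
               discounted_days_10y = c(b_ifc$discounted_disability_days,
                                       b_non$discounted_disability_days)),
    paths$burden, cfg)
  write_transition_csv(setup$m_non_ifc, paths$matrix_non_ifc)
  write_transition_csv(setup$m_ifc, paths$matrix_ifc)
  say("wrote %s", paste(unlist(paths), collapse = ", "))
  invisible(list(cohort = cohort, setup = setup,
                 trajectories = list(ifc = traj_ifc, non_ifc = traj_non),
                 burdens = list(ifc = b_ifc, non_ifc = b_non),
                 paths = paths))
}

#' Run the cost-effectiveness stage
#'
#' Projects both arms, accumulates burden, computes the incremental
#' cost-effectiveness results and writes a CSV plus a human-readable text
#' report shaped like the cost-effectiveness summary table (per-day DALY
#' with totals in parentheses, per-day costs with totals, ICER and
#' classification).
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list with the `ifc_cea_result`, the setup and the
#'   paths written.
#' @export
run_cea <- function(cfg = default_run_config(), out_dir = ".", quiet = FALSE) {
  validate_run_config(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  setup <- model_setup(cfg)
  w <- cfg$daly$disability_weights
  dw <- disability_weights(w[["mild"]], w[["moderate"]], w[["severe"]])
  d <- discount_spec(cfg$daly$discount$annual_rate,
                     cfg$daly$discount$grace_years)
  traj_ifc <- simulate_cohort_fractions(setup$init_ifc, setup$m_ifc, setup$spec)
  traj_non <- simulate_cohort_fractions(setup$init_non_ifc, setup$m_non_ifc,
                                        setup$spec)
  b_ifc <- disability_days(traj_ifc, dw, setup$spec, d)
  b_non <- disability_days(traj_non, dw, setup$spec, d)
  costs <- cost_inputs(cfg$costs$home_food_per_day,
                       cfg$costs$ifc_increment_per_day,
                       cfg$costs$intervention_months,
                       cfg$costs$days_per_month)
  res <- cea_summary(b_ifc, b_non, costs, setup$wtp)
  csv_path <- file.path(out_dir, "cea_result.csv")
  write_with_header(
    data.frame(quantity = c("cost_ifc", "cost_non_ifc", "incremental_cost",
                            "days_ifc", "days_non_ifc", "days_averted",
                            "daily_daly_ifc", "daily_daly_non_ifc",
                            "daily_daly_averted", "icer_per_day",
                            "icer_per_daly", "nmb"),
               value = c(res$cost_per_arm[["ifc"]],
                         res$cost_per_arm[["non_ifc"]],
                         res$incremental_cost,
                         res$effect_per_arm[["ifc"]],
                         res$effect_per_arm[["non_ifc"]],
                         res$days_averted,
                         res$daily_daly_per_arm[["ifc"]],
                         res$daily_daly_per_arm[["non_ifc"]],
                         res$daily_daly_averted,
                         res$icer_per_day, res$icer_per_daly, res$nmb)),
    csv_path, cfg)
  report_path <- file.path(out_dir, "cea_report.txt")
  horizon <- sprintf("%.0f years", res$horizon_years)
  lines <- c(
    sprintf("# config_digest: %s", config_digest(cfg)),
    sprintf("# seed: %d", cfg$seed),
    "Cost-effectiveness of iron-fortified infant cereals vs home foods only",
    "",
    sprintf("DALY with IFC per day (in %s):    %.3f (%.0f)", horizon,
            res$daily_daly_per_arm[["ifc"]], res$effect_per_arm[["ifc"]]),
    sprintf("DALY without IFC per day (in %s): %.3f (%.0f)", horizon,
            res$daily_daly_per_arm[["non_ifc"]],
            res$effect_per_arm[["non_ifc"]]),
    sprintf("Cost of food per person/day with IFC:    %.3f (%.1f) USD",
            costs$home_food_per_day + costs$ifc_increment_per_day,
            res$cost_per_arm[["ifc"]]),
    sprintf("Cost of food per person/day without IFC: %.3f (%.1f) USD",
            costs$home_food_per_day, res$cost_per_arm[["non_ifc"]]),
    sprintf("ICER (%s): %.2f USD per disability day averted [%s]", horizon,
            res$icer_per_day, res$quadrant),
    sprintf("Classification (WHO-CHOICE, threshold %.1f USD/day): %s",
            setup$wtp$multiplier * setup$wtp$gdp_per_capita_per_day,
            res$classification),
    sprintf("Net monetary benefit at threshold: %.2f USD", res$nmb))
  writeLines(lines, report_path)
  if (!quiet) message("wrote ", csv_path, " and ", report_path)
  invisible(list(result = res, setup = setup,
                 paths = list(csv = csv_path, report = report_path)))
}

#' Run the one-way sensitivity stage
#'
#' @inheritParams run_simulate
#' @param bounds As in [one_way_sa()]; `NULL` applies the config's
#'   relative bound (default +/-20%) to every scenario parameter.
#' @return Invisibly, the `ifc_oneway` table and the path written.
#' @export
run_oneway <- function(cfg = default_run_config(), out_dir = ".",
                       bounds = NULL, quiet = FALSE) {
  validate_run_config(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  setup <- model_setup(cfg)
  if (is.null(bounds)) {
    rel <- cfg$oneway$rel_bound %||% 0.2
    bounds <- lapply(setup$base_params,
                     function(v) c((1 - rel) * v, (1 + rel) * v))
  }
  tornado <- one_way_sa(setup, bounds)
  path <- file.path(out_dir, "tornado.csv")
  write_with_header(as.data.frame(tornado), path, cfg)
  if (!quiet) message("wrote ", path)
  invisible(list(tornado = tornado, path = path))
}

#' Run the probabilistic sensitivity stage
#'
#' Runs the PSA, writes the per-run samples, a summary (median ICER and
#' interquartile range) and the cost-effectiveness acceptability curve.
#'
#' @inheritParams run_simulate
#' @param n_runs Number of PSA runs; `NULL` uses the config's `psa.n_runs`.
#' @param wtp_grid WTP grid for the CEAC.
#' @return Invisibly, a list with the `ifc_psa`, the `ifc_ceac` and paths.
#' @export
run_psa_analysis <- function(cfg = default_run_config(), out_dir = ".",
                             n_runs = NULL, wtp_grid = seq(0, 20, by = 0.25),
                             quiet = FALSE) {
  validate_run_config(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  setup <- model_setup(cfg)
  n_runs <- n_runs %||% cfg$psa$n_runs
  psa <- run_psa(setup, n_runs = n_runs, seed = cfg$seed + 10L)
  curve <- ceac(psa, wtp_grid)
  paths <- list(samples = file.path(out_dir, "psa_samples.csv"),
                summary = file.path(out_dir, "psa_summary.csv"),
                ceac = file.path(out_dir, "ceac.csv"))
  write_with_header(psa$samples, paths$samples, cfg)
  write_with_header(
    data.frame(quantity = c("median_icer", "icer_q25", "icer_q75",
                            "n_runs", "n_failed"),
               value = c(psa$median_icer, psa$iqr_icer[1], psa$iqr_icer[2],
                         psa$n_runs, psa$n_failed)),
    paths$summary, cfg)
  write_with_header(as.data.frame(curve), paths$ceac, cfg)
  if (!quiet) {
    message(sprintf("PSA: %d runs (%d failed), median ICER %.3f [IQR %.3f, %.3f]",
                    psa$n_runs, psa$n_failed, psa$median_icer,
                    psa$iqr_icer[1], psa$iqr_icer[2]))
  }
  invisible(list(psa = psa, ceac = curve, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
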