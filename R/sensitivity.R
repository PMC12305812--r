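#' Fit a gamma distribution from a mean and 95% CI
#'
#' Method-of-moments parameterisation used for cost parameters in the
#' probabilistic sensitivity analysis: the SD is taken as
#' `(ci95_high - ci95_low) / 3.92` (normal-quantile width of a 95% CI),
#' then `shape = mean^2 / var` and `scale = var / mean`, so the fitted
#' mean `shape * scale` equals the input mean exactly.
#'
#' @param mean Positive mean.
#' @param ci95_low,ci95_high 95% interval bounds with
#'   `0 < ci95_low < mean < ci95_high`.
#' @return List with `shape`, `scale`, `mean`, `sd`.
#' @examples
#' fit_gamma_from_ci(0.17, 0.13, 0.21)
#' @export
fit_gamma_from_ci <- function(mean, ci95_low, ci95_high) {
  if (!(mean > 0)) stop("gamma mean must be positive", call. = FALSE)
  if (!(ci95_low < mean && mean < ci95_high) || ci95_low <= 0) {
    stop("need 0 < ci95_low < mean < ci95_high", call. = FALSE)
  }
  sd <- (ci95_high - ci95_low) / 3.92
  if (sd <= 0) stop("degenerate interval: variance must be positive",
                    call. = FALSE)
  v <- sd^2
  list(shape = mean^2 / v, scale = v / mean, mean = mean, sd = sd)
}

#' Fit a beta distribution from a mean and 95% CI
#'
#' Method-of-moments parameterisation used for probabilities, relative
#' risks (on (0,1)) and disability weights: with
#' `var = ((ci95_high - ci95_low)/3.92)^2`,
#' `alpha = mean * (mean (1 - mean) / var - 1)` and
#' `beta = (1 - mean) * (mean (1 - mean) / var - 1)`, so the fitted mean
#' `alpha / (alpha + beta)` equals the input mean exactly.
#'
#' @param mean Mean in (0, 1).
#' @param ci95_low,ci95_high 95% interval bounds inside (0, 1) bracketing
#'   the mean.
#' @return List with `alpha`, `beta`, `mean`, `sd`.
#' @export
fit_beta_from_ci <- function(mean, ci95_low, ci95_high) {
  if (!(mean > 0 && mean < 1)) stop("beta mean must lie in (0, 1)", call. = FALSE)
  if (!(ci95_low < mean && mean < ci95_high) ||
      ci95_low <= 0 || ci95_high >= 1) {
    stop("bounds must lie in (0, 1) and bracket the mean", call. = FALSE)
  }
  v <- ((ci95_high - ci95_low) / 3.92)^2
  if (v >= mean * (1 - mean)) {
    stop("variance too large for a beta distribution (var >= mean(1-mean))",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu, mean = mean, sd = sqrt(v))
}

#' Describe an uncertain model parameter
#'
#' @param name Parameter name (must match a scenario parameter understood
#'   by [evaluate_scenario()]).
#' @param kind `"gamma"` (costs), `"beta"` (probabilities, weights,
#'   relative risks) or `"fixed"`.
#' @param mean Central value.
#' @param ci95_low,ci95_high 95% interval (ignored for `"fixed"`).
#' @return List of class `ifc_param_distribution`.
#' @export
param_distribution <- function(name, kind = c("gamma", "beta", "fixed"),
                               mean, ci95_low = NA, ci95_high = NA) {
  kind <- match.arg(kind)
  if (kind == "gamma") fit_gamma_from_ci(mean, ci95_low, ci95_high)
  if (kind == "beta") fit_beta_from_ci(mean, ci95_low, ci95_high)
  structure(list(name = name, kind = kind, mean = mean,
                 ci95_low = ci95_low, ci95_high = ci95_high),
            class = "ifc_param_distribution")
}

draw_param <- function(dist, n = 1) {
  switch(dist$kind,
    fixed = rep(dist$mean, n),
    gamma = {
      f <- fit_gamma_from_ci(dist$mean, dist$ci95_low, dist$ci95_high)
      stats::rgamma(n, shape = f$shape, scale = f$scale)
    },
    beta = {
      f <- fit_beta_from_ci(dist$mean, dist$ci95_low, dist$ci95_high)
      stats::rbeta(n, f$alpha, f$beta)
    })
}

#' Evaluate one deterministic scenario of the full pipeline
#'
#' Runs the cohort-fraction pipeline for a named list of parameter
#' overrides on top of a model setup (see [model_setup()]): rebuilds the
#' arm matrices, projects both arms, accumulates disability days and
#' returns the incremental results. This is the unit of work for one-way
#' and probabilistic sensitivity analysis.
#'
#' Recognised parameters: `home_food_per_day`, `ifc_increment_per_day`,
#' `rr_ifc`, `recovery_multiplier`, `dw_mild`, `dw_moderate`, `dw_severe`,
#' `discount_rate`.
#'
#' @param setup A [model_setup()].
#' @param params Named list/vector of overrides; missing entries use the
#'   setup's base values.
#' @return List with `delta_cost`, `delta_effect` (disability days
#'   averted), `icer`, and per-arm burdens.
#' @export
evaluate_scenario <- function(setup, params = list()) {
  stopifnot(inherits(setup, "ifc_model_setup"))
  base <- setup$base_params
  p <- utils::modifyList(base, as.list(params))
  bad <- setdiff(names(p), names(base))
  if (length(bad) > 0) {
    stop("unknown scenario parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (p$rr_ifc < 0 || p$recovery_multiplier < 0 ||
      min(p$home_food_per_day, p$ifc_increment_per_day) < 0 ||
      min(p$dw_mild, p$dw_moderate, p$dw_severe) < 0 ||
      max(p$dw_mild, p$dw_moderate, p$dw_severe) > 1 ||
      p$discount_rate < 0 || p$discount_rate >= 1) {
    stop("scenario parameter outside its valid range", call. = FALSE)
  }
  m_non <- build_transition_matrix(setup$worsening_rates,
                                   p$recovery_multiplier * setup$recovery_pattern,
                                   arm = "non-IFC")
  m_ifc <- apply_relative_risk(m_non, p$rr_ifc, arm = "IFC")
  w <- disability_weights(p$dw_mild, p$dw_moderate, p$dw_severe)
  d <- discount_spec(annual_rate = p$discount_rate,
                     grace_years = setup$grace_years)
  traj_ifc <- simulate_cohort_fractions(setup$init_ifc, m_ifc, setup$spec)
  traj_non <- simulate_cohort_fractions(setup$init_non_ifc, m_non, setup$spec)
  b_ifc <- disability_days(traj_ifc, w, setup$spec, d)
  b_non <- disability_days(traj_non, w, setup$spec, d)
  costs <- cost_inputs(p$home_food_per_day, p$ifc_increment_per_day,
                       setup$intervention_months, setup$days_per_month)
  delta_cost <- total_food_cost(costs, TRUE) - total_food_cost(costs, FALSE)
  delta_effect <- b_non$disability_days - b_ifc$disability_days
  list(delta_cost = delta_cost,
       delta_effect = delta_effect,
       icer = if (delta_effect != 0) delta_cost / -delta_effect else NA_real_,
       burden_ifc = b_ifc, burden_non_ifc = b_non)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the deterministic pipeline once per bound per parameter, all
#' other parameters at base, and reports the ICER at each bound together
#' with the swing `|high_icer - low_icer|`, sorted by descending swing.
#' Default bounds are +/-20% around each cost parameter, mirroring the
#' cost-reduction scenarios of interest, and +/-20% (relative) on the
#' transition-rate parameters.
#'
#' @param setup A [model_setup()].
#' @param bounds Named list of `c(low, high)` bounds per parameter;
#'   `NULL` uses +/-20% relative bounds on all non-fixed base parameters.
#' @return Data frame of class `ifc_oneway` with columns parameter,
#'   low, high, low_icer, base_icer, high_icer, swing.
#' @export
one_way_sa <- function(setup, bounds = NULL) {
  stopifnot(inherits(setup, "ifc_model_setup"))
  base <- setup$base_params
  if (is.null(bounds)) {
    bounds <- lapply(base, function(v) c(0.8 * v, 1.2 * v))
  }
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || b[1] > base[[nm]] || b[2] < base[[nm]]) {
      stop(sprintf("bounds for '%s' must bracket the base value", nm),
           call. = FALSE)
    }
    if (any(b < 0)) stop("bounds must be non-negative", call. = FALSE)
  }
  base_icer <- evaluate_scenario(setup)$icer
  rows <- lapply(names(bounds), function(nm) {
    b <- bounds[[nm]]
    lo <- evaluate_scenario(setup, stats::setNames(list(b[1]), nm))$icer
    hi <- evaluate_scenario(setup, stats::setNames(list(b[2]), nm))$icer
    data.frame(parameter = nm, low = b[1], high = b[2],
               low_icer = lo, base_icer = base_icer, high_icer = hi,
               swing = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  class(out) <- c("ifc_oneway", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws every non-fixed parameter from its distribution (gamma for
#' costs, beta for everything else), evaluates the deterministic
#' cohort-fraction pipeline per draw, and records the incremental cost,
#' incremental effect and ICER of each run. Runs whose drawn parameters
#' fail validation are recorded as failed with the reason and excluded
#' from summaries. Per-draw projection is deterministic so the PSA spread
#' reflects parameter uncertainty, not microsimulation noise.
#'
#' @param setup A [model_setup()].
#' @param distributions List of [param_distribution()] objects; `NULL`
#'   uses the setup's defaults (+/-20% 95% CIs on costs, disability
#'   weights and the IFC relative risk).
#' @param n_runs Number of PSA runs (default 1000).
#' @param seed Integer seed.
#' @return List of class `ifc_psa` with `samples` (data frame run,
#'   delta_cost, delta_effect, icer), `median_icer`, `iqr_icer`,
#'   `n_runs`, `n_failed`, `failures`, `seed`.
#' @export
run_psa <- function(setup, distributions = NULL, n_runs = 1000, seed = 1L) {
  stopifnot(inherits(setup, "ifc_model_setup"))
  if (is.null(distributions)) distributions <- default_psa_distributions(setup)
  nms <- vapply(distributions, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate parameter distributions", call. = FALSE)
  set.seed(as.integer(seed))
  draws <- sapply(distributions, draw_param, n = n_runs)
  if (n_runs == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- nms
  samples <- data.frame(run = seq_len(n_runs), delta_cost = NA_real_,
                        delta_effect = NA_real_, icer = NA_real_)
  failures <- character(0)
  for (i in seq_len(n_runs)) {
    res <- tryCatch(evaluate_scenario(setup, as.list(draws[i, ])),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("run %d: %s", i, conditionMessage(res)))
      next
    }
    samples$delta_cost[i] <- res$delta_cost
    samples$delta_effect[i] <- res$delta_effect
    samples$icer[i] <- res$icer
  }
  ok <- !is.na(samples$icer)
  structure(list(samples = samples,
                 median_icer = stats::median(samples$icer[ok]),
                 iqr_icer = unname(stats::quantile(samples$icer[ok],
                                                   c(0.25, 0.75))),
                 n_runs = n_runs, n_failed = sum(!ok), failures = failures,
                 seed = as.integer(seed)),
            class = "ifc_psa")
}

default_psa_distributions <- function(setup) {
  p <- setup$base_params
  rel_ci <- function(v) c(0.8 * v, 1.2 * v)
  mk_gamma <- function(nm) {
    ci <- rel_ci(p[[nm]])
    param_distribution(nm, "gamma", p[[nm]], ci[1], ci[2])
  }
  mk_beta <- function(nm) {
    ci <- rel_ci(p[[nm]])
    param_distribution(nm, "beta", p[[nm]], ci[1], min(ci[2], 0.999))
  }
  list(mk_gamma("home_food_per_day"),
       mk_gamma("ifc_increment_per_day"),
       mk_beta("rr_ifc"),
       mk_beta("dw_mild"), mk_beta("dw_moderate"), mk_beta("dw_severe"))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the
#' intervention is acceptable: the fraction of successful PSA runs with
#' `net_monetary_benefit(delta_effect, delta_cost, wtp) >= 0`. The curve
#' is non-decreasing in WTP whenever all runs avert burden.
#'
#' @param psa An `ifc_psa` result with at least one successful run.
#' @param wtp_grid Non-negative WTP values (USD per disability day
#'   averted); default 0 to 20 by 0.25.
#' @return Data frame of class `ifc_ceac` with columns `wtp` and
#'   `p_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 20, by = 0.25)) {
  stopifnot(inherits(psa, "ifc_psa"))
  ok <- !is.na(psa$samples$icer)
  if (!any(ok)) stop("PSA has no successful runs", call. = FALSE)
  de <- psa$samples$delta_effect[ok]
  dc <- psa$samples$delta_cost[ok]
  p <- vapply(wtp_grid, function(l) {
    mean(net_monetary_benefit(de, dc, l) >= 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, p_cost_effective = p),
            class = c("ifc_ceac", "data.frame"))
}

#' Subgroup-stratified PSA
#'
#' Repeats the PSA with baseline occupancy taken from a subgroup of the
#' cohort (e.g. one sex or one wealth quintile), holding all parameter
#' distributions fixed, and reports the per-subgroup median ICER and IQR.
#'
#' @param setup A [model_setup()].
#' @param cohort The `ifc_cohort` the setup's baselines came from.
#' @param by `"sex"` or `"wealth_quintile"`.
#' @param distributions As in [run_psa()].
#' @param n_runs,seed As in [run_psa()].
#' @return Data frame with one row per subgroup: group, median_icer,
#'   q25, q75, n_children.
#' @export
run_psa_stratified <- function(setup, cohort, by = c("sex", "wealth_quintile"),
                               distributions = NULL, n_runs = 200, seed = 1L) {
  by <- match.arg(by)
  validate_cohort(cohort)
  groups <- sort(unique(cohort[[by]]))
  rows <- lapply(seq_along(groups), function(g_i) {
    g <- groups[g_i]
    sub <- cohort[cohort[[by]] == g, , drop = FALSE]
    sub_setup <- setup
    # common subgroup baseline: arms differ by treatment, not by start
    sub_setup$init_ifc <- sub_setup$init_non_ifc <- state_occupancy(sub)
    psa <- run_psa(sub_setup, distributions, n_runs,
                   seed = as.integer(seed) + g_i)
    data.frame(group = as.character(g), median_icer = psa$median_icer,
               q25 = psa$iqr_icer[1], q75 = psa$iqr_icer[2],
               n_children = nrow(sub), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
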