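test_that("gamma fit recovers the input mean exactly and in simulation", {
  f <- fit_gamma_from_ci(0.17, 0.13, 0.21)
  expect_equal(f$shape * f$scale, 0.17, tolerance = 1e-9)
  expect_equal(f$sd, (0.21 - 0.13) / 3.92, tolerance = 1e-12)
  expect_error(fit_gamma_from_ci(0.17, 0.17, 0.17), "ci95_low < mean")

  withr::local_seed(1)
  x <- rgamma(1e5, shape = f$shape, scale = f$scale)
  se <- f$sd / sqrt(1e5)
  expect_lt(abs(mean(x) - 0.17), 3 * se)
})

test_that("beta fit recovers the input mean, symmetry and simulated mean", {
  f <- fit_beta_from_ci(0.5, 0.4, 0.6)
  expect_equal(f$alpha, f$beta, tolerance = 1e-9)
  expect_equal(f$alpha / (f$alpha + f$beta), 0.5, tolerance = 1e-9)

  g <- fit_beta_from_ci(0.2, 0.15, 0.25)
  expect_equal(g$alpha / (g$alpha + g$beta), 0.2, tolerance = 1e-9)
  expect_error(fit_beta_from_ci(0.01, 0.005, 0.6), "variance too large")
  expect_error(fit_beta_from_ci(1.2, 0.1, 0.9), "\\(0, 1\\)")

  withr::local_seed(2)
  x <- rbeta(1e5, g$alpha, g$beta)
  expect_lt(abs(mean(x) - 0.2), 3 * g$sd / sqrt(1e5))
})

make_setup <- function() {
  model_setup(default_run_config(expand_n = 2000, seed = 5))
}

test_that("one-way analysis: swings match direct pipeline calls and sort descending", {
  setup <- make_setup()
  bounds <- list(ifc_increment_per_day = c(0.13, 0.21),
                 dw_moderate = c(0.04, 0.06),
                 rr_ifc = 0.67 * c(0.9, 1.1))
  bounds$rr_ifc <- c(0.8, 1.2) * setup$base_params$rr_ifc
  tor <- one_way_sa(setup, bounds)
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(tor$swing) <= 0))
  for (i in seq_len(nrow(tor))) {
    nm <- tor$parameter[i]
    lo <- evaluate_scenario(setup, stats::setNames(list(tor$low[i]), nm))$icer
    hi <- evaluate_scenario(setup, stats::setNames(list(tor$high[i]), nm))$icer
    expect_equal(tor$swing[i], abs(hi - lo), tolerance = 1e-12)
  }
})

test_that("zero-width bounds give zero swing and cost parameters behave as expected", {
  setup <- make_setup()
  base <- setup$base_params
  tor <- one_way_sa(setup, list(
    ifc_increment_per_day = c(base$ifc_increment_per_day,
                              base$ifc_increment_per_day),
    home_food_per_day = c(0.8, 1.2) * base$home_food_per_day))
  expect_equal(tor$swing[tor$parameter == "ifc_increment_per_day"], 0)
  # home food cost is common to both arms, so it cannot move the ICER
  expect_equal(tor$swing[tor$parameter == "home_food_per_day"], 0)

  # under +/-20% bounds on the cost parameters, the IFC increment dominates
  cost_tor <- one_way_sa(setup, list(
    home_food_per_day = c(0.8, 1.2) * base$home_food_per_day,
    ifc_increment_per_day = c(0.8, 1.2) * base$ifc_increment_per_day))
  expect_equal(cost_tor$parameter[1], "ifc_increment_per_day")
  expect_gt(cost_tor$swing[1], 0)

  expect_error(one_way_sa(setup, list(rr_ifc = c(0.9, 0.95))), "bracket")
})

test_that("PSA with all-fixed distributions collapses to the deterministic result", {
  setup <- make_setup()
  fixed <- lapply(names(setup$base_params)[1:3], function(nm) {
    param_distribution(nm, "fixed", setup$base_params[[nm]])
  })
  psa <- run_psa(setup, fixed, n_runs = 20, seed = 4)
  det <- evaluate_scenario(setup)
  expect_equal(psa$n_failed, 0)
  expect_true(all(abs(psa$samples$icer - det$icer) < 1e-12))
  expect_equal(psa$median_icer, det$icer, tolerance = 1e-12)
})

test_that("PSA is seed-deterministic and medians drift to the deterministic ICER as spread shrinks", {
  setup <- make_setup()
  a <- run_psa(setup, n_runs = 50, seed = 10)
  b <- run_psa(setup, n_runs = 50, seed = 10)
  expect_identical(a$samples, b$samples)
  expect_true(a$median_icer >= a$iqr_icer[1] && a$median_icer <= a$iqr_icer[2])

  det <- evaluate_scenario(setup)$icer
  narrow <- function(hw) {
    p <- setup$base_params
    dists <- list(
      param_distribution("ifc_increment_per_day", "gamma",
                         p$ifc_increment_per_day,
                         (1 - hw) * p$ifc_increment_per_day,
                         (1 + hw) * p$ifc_increment_per_day),
      param_distribution("rr_ifc", "beta", p$rr_ifc,
                         (1 - hw) * p$rr_ifc, (1 + hw) * p$rr_ifc))
    run_psa(setup, dists, n_runs = 50, seed = 11)$median_icer
  }
  err <- abs(c(narrow(0.2), narrow(0.05), narrow(0.01)) - det)
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.05 * abs(det))
})

test_that("CEAC equals a counting oracle, is monotone, and has the right limits", {
  setup <- make_setup()
  psa <- run_psa(setup, n_runs = 200, seed = 12)
  grid <- seq(0, 40, by = 1)
  curve <- ceac(psa, grid)
  expect_true(!is.unsorted(curve$p_cost_effective))
  expect_true(all(curve$p_cost_effective >= 0 & curve$p_cost_effective <= 1))

  ok <- !is.na(psa$samples$icer)
  de <- psa$samples$delta_effect[ok]; dc <- psa$samples$delta_cost[ok]
  for (i in seq_along(grid)) {
    count <- sum(grid[i] * de - dc >= 0) / length(de)
    expect_equal(curve$p_cost_effective[i], count, tolerance = 1e-12)
  }
  # all runs cost more at WTP 0; all avert burden so p -> 1 at huge WTP
  expect_equal(curve$p_cost_effective[1], 0)
  expect_true(all(de > 0))
  expect_equal(ceac(psa, 1e6)$p_cost_effective, 1)
})

test_that("stratified PSA reports one row per subgroup", {
  cfg <- default_run_config(expand_n = 4000, seed = 6)
  sim <- run_simulate(cfg, withr::local_tempdir(), quiet = TRUE)
  strat <- run_psa_stratified(sim$setup, sim$cohort, by = "sex",
                              n_runs = 20, seed = 3)
  expect_equal(nrow(strat), 2)
  expect_setequal(strat$group, c("boy", "girl"))
  expect_true(all(is.finite(strat$median_icer)))
})
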