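test_that("rate/probability conversion matches the closed form and inverts", {
  expect_equal(rate_to_probability(0, 5), 0)
  expect_equal(rate_to_probability(0.5, 0.5), 0.2211992, tolerance = 1e-6)
  for (r in c(0.01, 0.1, 0.5, 1, 2)) {
    expect_equal(probability_to_rate(rate_to_probability(r, 0.7), 0.7), r,
                 tolerance = 1e-12)
  }
  expect_error(rate_to_probability(-1), "non-negative")
  expect_error(probability_to_rate(1), "infinite")
})

test_that("built matrices are row-stochastic and adjacency-restricted", {
  withr::local_seed(1)
  for (i in 1:20) {
    m <- random_adjacent_matrix()
    expect_true(all(abs(rowSums(m) - 1) < 1e-9))
    expect_true(all(m >= 0 & m <= 1))
    # no jumps over more than one severity level
    expect_equal(m[1, 3], 0); expect_equal(m[1, 4], 0)
    expect_equal(m[2, 4], 0); expect_equal(m[3, 1], 0)
    expect_equal(m[4, 1], 0); expect_equal(m[4, 2], 0)
  }
})

test_that("relative-risk adjustment matches elementwise rate-space recomputation", {
  m <- make_test_matrix()
  expect_equal(unclass(apply_relative_risk(m, 1)), unclass(m),
               tolerance = 1e-12)
  m0 <- apply_relative_risk(m, 0)
  expect_equal(m0[1, 2], 0); expect_equal(m0[2, 3], 0); expect_equal(m0[3, 4], 0)

  rr <- 0.5
  adj <- apply_relative_risk(m, rr)
  for (i in 1:3) {
    j <- i + 1
    expect_equal(adj[i, j], 1 - exp(-rr * (-log(1 - m[i, j]))),
                 tolerance = 1e-12)
    expect_equal(adj[j, i], m[j, i])  # recovery untouched
  }
  expect_true(all(abs(rowSums(adj) - 1) < 1e-9))
})

test_that("cohort-fraction projection equals an explicit matrix-product loop", {
  spec <- trajectory_spec(n_cycles = 20)
  id <- build_transition_matrix(c(0, 0, 0), c(0, 0, 0))
  init <- c(0.4, 0.3, 0.25, 0.05)
  traj <- simulate_cohort_fractions(init, id, spec)
  expect_true(all(apply(unclass(traj), 1, function(r) all(r == init))))

  absorb <- ifcsim:::new_transition_matrix(
    matrix(rep(c(1, 0, 0, 0), 4), 4, byrow = TRUE), "test")
  traj2 <- simulate_cohort_fractions(init, absorb, spec)
  expect_true(all(prevalence(traj2) == 0))

  withr::local_seed(42)
  for (k in 1:5) {
    m <- random_adjacent_matrix()
    init <- random_occupancy()
    traj <- simulate_cohort_fractions(init, m, spec)
    cur <- init
    for (t in 1:20) {
      cur <- as.numeric(cur %*% unclass(m))
      expect_equal(unname(unclass(traj)[t, ]), cur, tolerance = 1e-12)
    }
    expect_true(all(abs(rowSums(unclass(traj)) - 1) < 1e-9))
  }
})

test_that("prevalence is the anaemic occupancy mass", {
  expect_equal(prevalence(c(0.413, 0.240, 0.336, 0.011)), 0.587)
  expect_equal(prevalence(c(1, 0, 0, 0)), 0)
  expect_equal(prevalence(c(0, 0, 0, 1)), 1)
  expect_error(prevalence(c(0.5, 0.5, 0.5, 0.5)), "summing to 1")
})

test_that("microsimulation agrees with the deterministic projection at large n", {
  cfg <- test_config(expand_n = 20000)
  spec_pop <- base_population_spec()
  base <- sample_base_cohort(spec_pop, seed = 5)
  cohort <- expand_cohort(base, 20000, seed = 6)
  m_non <- make_test_matrix()
  m_ifc <- apply_relative_risk(m_non, 0.6, arm = "IFC")
  tspec <- trajectory_spec(n_cycles = 10)
  micro <- simulate_individuals(cohort, list(ifc = m_ifc, non_ifc = m_non),
                                tspec, seed = 9)
  for (arm in c("ifc", "non_ifc")) {
    m <- if (arm == "ifc") m_ifc else m_non
    init <- state_occupancy(cohort, ifc = (arm == "ifc"))
    det <- simulate_cohort_fractions(init, m, tspec)
    n_arm <- sum(cohort$ifc == (arm == "ifc"))
    dev <- abs(unclass(micro[[arm]]) - unclass(det))
    se <- sqrt(unclass(det) * (1 - unclass(det)) / n_arm)
    expect_true(all(dev <= 3 * pmax(se, 1e-12) + 1e-12),
                label = sprintf("microsim within 3 SE (%s arm)", arm))
  }
})

test_that("microsimulation is seed-deterministic and frozen under the identity matrix", {
  cohort <- expand_cohort(make_count_cohort(none = 30, mild = 30,
                                            moderate = 30, severe = 10,
                                            ifc_every = 4), 400, seed = 2)
  id <- build_transition_matrix(c(0, 0, 0), c(0, 0, 0))
  tspec <- trajectory_spec(n_cycles = 5)
  a <- simulate_individuals(cohort, list(ifc = id, non_ifc = id), tspec, seed = 3)
  b <- simulate_individuals(cohort, list(ifc = id, non_ifc = id), tspec, seed = 3)
  expect_identical(a, b)
  for (arm in c("ifc", "non_ifc")) {
    init <- state_occupancy(cohort, ifc = (arm == "ifc"))
    expect_true(all(apply(unclass(a[[arm]]), 1,
                          function(r) all(abs(r - init) < 1e-12))))
  }
})

test_that("calibration hits its end-prevalence target and bisection is monotone", {
  cal <- calibrate_transitions(0.57, 0.36, n_cycles = 20)
  expect_lt(abs(cal$achieved_prev - 0.36), 1e-4)
  traj <- simulate_cohort_fractions(cal$init, cal$matrix, trajectory_spec(20))
  expect_lt(abs(prevalence(traj)[20] - 0.36), 1e-4)

  # monotonicity: larger recovery multiplier => lower end prevalence
  ends <- sapply(c(0.5, 1, 2) * cal$multiplier, function(k) {
    m <- build_transition_matrix(c(0.10, 0.06, 0.010),
                                 k * c(1.0, 0.7, 0.7))
    prevalence(simulate_cohort_fractions(cal$init, m, trajectory_spec(20)))[20]
  })
  expect_true(all(diff(ends) < 0))

  # flat target with no worsening accepts a zero recovery rate
  flat <- calibrate_transitions(0.4, 0.4, n_cycles = 10,
                                worsening_rates = c(0, 0, 0))
  expect_equal(flat$multiplier, 0)

  expect_error(calibrate_transitions(0.5, 0.01, n_cycles = 2),
               "unreachable")
})

test_that("relative-risk calibration reaches the IFC target below the non-IFC arm", {
  cal <- calibrate_transitions(0.57, 0.36)
  ifc <- calibrate_relative_risk(cal$matrix, 0.59, 0.27)
  expect_lt(abs(ifc$achieved_prev - 0.27), 1e-4)
  expect_lt(ifc$rr, 1)

  # dominance at every cycle from a common baseline
  init <- ifcsim:::occupancy_from_prevalence(0.587)
  spec <- trajectory_spec(20)
  p_non <- prevalence(simulate_cohort_fractions(init, cal$matrix, spec))
  p_ifc <- prevalence(simulate_cohort_fractions(init, ifc$matrix, spec))
  expect_true(all(p_ifc <= p_non))
})

test_that("transition matrices round-trip through CSV", {
  m <- make_test_matrix(arm = "IFC")
  path <- withr::local_tempfile(fileext = ".csv")
  write_transition_csv(m, path)
  back <- read_transition_csv(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  expect_equal(attr(back, "arm"), "IFC")
})
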