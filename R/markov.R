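#' Convert an event rate to a per-cycle transition probability
#'
#' Standard exponential conversion `p = 1 - exp(-rate * t)` used when
#' transition probabilities are derived from rates at which individuals
#' move between health states, with [probability_to_rate()] as its inverse
#' `r = -log(1 - p) / t`.
#'
#' @param rate Non-negative event rate per unit time. Vectorised.
#' @param t Time at risk in the same units (default one cycle).
#' @return Probability in `[0, 1)`.
#' @examples
#' rate_to_probability(0.5, 0.5)  # 1 - exp(-0.25)
#' @export
rate_to_probability <- function(rate, t = 1) {
  if (any(rate < 0)) stop("`rate` must be non-negative", call. = FALSE)
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  1 - exp(-rate * t)
}

#' @rdname rate_to_probability
#' @param p Probability in `[0, 1)`.
#' @export
probability_to_rate <- function(p, t = 1) {
  if (any(p < 0) || any(p >= 1)) {
    stop("`p` must lie in [0, 1); p = 1 implies an infinite rate",
         call. = FALSE)
  }
  -log(1 - p) / t
}

new_transition_matrix <- function(p, arm) {
  dimnames(p) <- list(from = anaemia_states(), to = anaemia_states())
  structure(p, arm = arm, class = c("ifc_transition_matrix", "matrix", "array"))
}

#' Build a per-cycle transition matrix from worsening and recovery rates
#'
#' Constructs the 4x4 row-stochastic matrix over anaemia severity states
#' for one six-month cycle. Only adjacent-severity moves are allowed per
#' cycle (none <-> mild <-> moderate <-> severe). Probabilities follow the
#' competing-risks conversion: a state with total exit rate `R` keeps
#' probability `exp(-R)` and distributes `1 - exp(-R)` across its exits in
#' proportion to their rates, so rows are stochastic for any non-negative
#' rates.
#'
#' @param worsening_rates Numeric 3-vector of per-cycle rates for
#'   none->mild, mild->moderate, moderate->severe.
#' @param recovery_rates Numeric 3-vector of per-cycle rates for
#'   mild->none, moderate->mild, severe->moderate.
#' @param arm Arm label, `"non-IFC"` or `"IFC"`.
#' @return An `ifc_transition_matrix`.
#' @export
build_transition_matrix <- function(worsening_rates, recovery_rates,
                                    arm = "non-IFC") {
  stopifnot(length(worsening_rates) == 3, length(recovery_rates) == 3)
  if (any(worsening_rates < 0) || any(recovery_rates < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  m <- matrix(0, 4, 4)
  for (i in 1:4) {
    r_up <- if (i < 4) worsening_rates[i] else 0
    r_down <- if (i > 1) recovery_rates[i - 1] else 0
    total <- r_up + r_down
    if (total == 0) {
      m[i, i] <- 1
      next
    }
    p_exit <- rate_to_probability(total)
    if (i < 4) m[i, i + 1] <- p_exit * r_up / total
    if (i > 1) m[i, i - 1] <- p_exit * r_down / total
    m[i, i] <- 1 - p_exit
  }
  validate_transition_matrix(new_transition_matrix(m, arm))
}

validate_transition_matrix <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(4, 4))) {
    stop("transition matrix must be 4x4", call. = FALSE)
  }
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  m
}

#' Scale worsening transitions by a relative risk
#'
#' Applies a literature-derived relative risk to all transitions toward
#' higher severity: each worsening probability is converted to a rate,
#' multiplied by `rr`, converted back, and the diagonal is re-normalised so
#' rows still sum to 1. Improving transitions are unchanged. This is how
#' the IFC arm's matrix is derived from the non-IFC matrix.
#'
#' @param m An `ifc_transition_matrix`.
#' @param rr Positive relative risk on worsening rates (`rr < 1` protects).
#' @param arm Arm label for the result (default keeps `m`'s label).
#' @return An `ifc_transition_matrix`.
#' @export
apply_relative_risk <- function(m, rr, arm = attr(m, "arm")) {
  validate_transition_matrix(m)
  if (!is.numeric(rr) || length(rr) != 1 || rr < 0) {
    stop("`rr` must be a single non-negative number", call. = FALSE)
  }
  out <- unclass(m)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      if (out[i, j] > 0) {
        out[i, j] <- rate_to_probability(rr * probability_to_rate(m[i, j]))
      }
    }
  }
  for (i in 1:4) {
    off <- sum(out[i, -i])
    if (off > 1) {
      stop(sprintf("row %d off-diagonal mass %.4f > 1 after adjustment",
                   i, off), call. = FALSE)
    }
    out[i, i] <- 1 - off
  }
  validate_transition_matrix(new_transition_matrix(out, arm))
}

new_trajectory <- function(occ, arm, init) {
  dimnames(occ) <- list(cycle = seq_len(nrow(occ)), state = anaemia_states())
  structure(occ, arm = arm, init = init,
            class = c("ifc_trajectory", "matrix", "array"))
}

#' Trajectory settings
#'
#' @param n_cycles Number of six-month cycles (default 20, i.e. 10 years).
#' @param cycle_days Days per cycle (default 182.5).
#' @param mode `"cohort_fractions"` for the deterministic projection or
#'   `"individual_microsim"` for per-child simulation.
#' @return A validated list of class `ifc_trajectory_spec`.
#' @export
trajectory_spec <- function(n_cycles = 20, cycle_days = 182.5,
                            mode = c("cohort_fractions", "individual_microsim")) {
  mode <- match.arg(mode)
  if (n_cycles < 1) stop("`n_cycles` must be at least 1", call. = FALSE)
  if (cycle_days <= 0) stop("`cycle_days` must be positive", call. = FALSE)
  structure(list(n_cycles = as.integer(n_cycles), cycle_days = cycle_days,
                 mode = mode),
            class = "ifc_trajectory_spec")
}

#' Deterministic cohort-fraction projection
#'
#' Projects state occupancy forward: `occupancy[t] = init %*% m^t` for
#' t = 1..n_cycles.
#'
#' @param init Occupancy 4-vector summing to 1 (e.g. from
#'   [state_occupancy()]).
#' @param m An `ifc_transition_matrix`.
#' @param spec A [trajectory_spec()].
#' @return An `ifc_trajectory`: n_cycles x 4 matrix of occupancy fractions,
#'   rows summing to 1.
#' @export
simulate_cohort_fractions <- function(init, m, spec = trajectory_spec()) {
  if (length(init) != 4) stop("`init` must be a 4-vector", call. = FALSE)
  if (abs(sum(init) - 1) > 1e-9 || any(init < 0)) {
    stop("`init` must be a probability vector summing to 1", call. = FALSE)
  }
  validate_transition_matrix(m)
  occ <- matrix(NA_real_, spec$n_cycles, 4)
  cur <- as.numeric(init)
  for (t in seq_len(spec$n_cycles)) {
    cur <- as.numeric(cur %*% unclass(m))
    occ[t, ] <- cur
  }
  new_trajectory(occ, attr(m, "arm"), as.numeric(init))
}

#' Individual-level microsimulation of both arms
#'
#' Simulates each child's anaemia state cycle by cycle: a child's next
#' state is drawn from its current state's row of its arm's transition
#' matrix. Children with `ifc = TRUE` follow the IFC matrix, the rest the
#' non-IFC matrix. Returns the empirical per-cycle occupancy per arm,
#' which converges to [simulate_cohort_fractions()] at large n.
#'
#' @param cohort An `ifc_cohort` (its `state` column gives initial states).
#' @param m_by_arm Named list `list(ifc = , non_ifc = )` of transition
#'   matrices.
#' @param spec A [trajectory_spec()].
#' @param seed Integer seed; same seed reproduces trajectories exactly.
#' @return Named list of `ifc_trajectory` objects, one per arm.
#' @export
simulate_individuals <- function(cohort, m_by_arm, spec = trajectory_spec(),
                                 seed = 1L) {
  validate_cohort(cohort)
  if (!all(c("ifc", "non_ifc") %in% names(m_by_arm))) {
    stop("`m_by_arm` must have elements `ifc` and `non_ifc`", call. = FALSE)
  }
  lapply(m_by_arm, validate_transition_matrix)
  set.seed(as.integer(seed))
  states <- anaemia_states()
  out <- list()
  for (arm in c("ifc", "non_ifc")) {
    children <- cohort[cohort$ifc == (arm == "ifc"), , drop = FALSE]
    if (nrow(children) == 0) {
      stop(sprintf("cohort has no children in arm '%s'", arm), call. = FALSE)
    }
    m <- unclass(m_by_arm[[arm]])
    cum <- t(apply(m, 1, cumsum))
    cur <- as.integer(factor(children$state, levels = states))
    n <- length(cur)
    occ <- matrix(NA_real_, spec$n_cycles, 4)
    for (t in seq_len(spec$n_cycles)) {
      u <- stats::runif(n)
      # next state = first column whose cumulative probability exceeds u
      nxt <- 1L + rowSums(u > cum[cur, , drop = FALSE])
      cur <- pmin(nxt, 4L)
      occ[t, ] <- tabulate(cur, nbins = 4) / n
    }
    out[[arm]] <- new_trajectory(occ, ifelse(arm == "ifc", "IFC", "non-IFC"),
                                 state_occupancy(cohort, ifc = (arm == "ifc")))
  }
  out
}

#' Anaemia prevalence of an occupancy vector or trajectory
#'
#' Prevalence is the fraction of the cohort in any anaemic state, i.e.
#' `1 - occupancy["none"]`.
#'
#' @param occupancy Occupancy 4-vector summing to 1, or an
#'   `ifc_trajectory` (returns the per-cycle prevalence vector).
#' @return Numeric prevalence in `[0, 1]`.
#' @export
prevalence <- function(occupancy) {
  if (inherits(occupancy, "ifc_trajectory")) {
    return(1 - unclass(occupancy)[, 1])
  }
  if (length(occupancy) != 4 || abs(sum(occupancy) - 1) > 1e-9) {
    stop("`occupancy` must be a 4-vector summing to 1", call. = FALSE)
  }
  1 - occupancy[[1]]
}

# Initial occupancy from a prevalence and the conditional severity mix
# among anaemic children (defaults to the base-sample mix 410/574/18).
occupancy_from_prevalence <- function(prev,
                                      anaemic_shares = c(410, 574, 18) / 1002) {
  stopifnot(prev > 0, prev < 1, abs(sum(anaemic_shares) - 1) < 1e-9)
  c(1 - prev, prev * anaemic_shares)
}

#' Calibrate a transition matrix to hit a target end prevalence
#'
#' The literature gives transition-probability equations only indirectly;
#' this routine solves for the per-cycle matrix consistent with an observed
#' prevalence path: worsening rates are held fixed and a single scalar
#' multiplier on the recovery rates is found by bisection so that the
#' projected prevalence after `n_cycles` cycles matches `end_prev`.
#' End prevalence is strictly decreasing in the recovery multiplier, which
#' makes the bisection valid.
#'
#' @param start_prev Baseline anaemia prevalence in (0, 1).
#' @param end_prev Target prevalence after `n_cycles` in (0, 1).
#' @param n_cycles Number of cycles (default 20).
#' @param worsening_rates Fixed per-cycle worsening rates (none->mild,
#'   mild->moderate, moderate->severe).
#' @param recovery_pattern Relative pattern of the three recovery rates;
#'   the calibrated matrix uses `multiplier * recovery_pattern`.
#' @param anaemic_shares Severity mix among anaemic children at baseline.
#' @param arm Arm label for the returned matrix.
#' @param tol_multiplier Bisection tolerance on the multiplier (default 1e-6).
#' @param tol_prevalence Required accuracy of the achieved end prevalence
#'   (default 1e-4).
#' @param bracket Search interval for the multiplier.
#' @return List with `matrix` (the calibrated `ifc_transition_matrix`),
#'   `multiplier`, `achieved_prev`, `init` (baseline occupancy) and
#'   `iterations`.
#' @export
calibrate_transitions <- function(start_prev, end_prev, n_cycles = 20,
                                  worsening_rates = c(0.10, 0.06, 0.010),
                                  recovery_pattern = c(1.0, 0.7, 0.7),
                                  anaemic_shares = c(410, 574, 18) / 1002,
                                  arm = "non-IFC",
                                  tol_multiplier = 1e-6,
                                  tol_prevalence = 1e-4,
                                  bracket = c(0, 20)) {
  stopifnot(start_prev > 0, start_prev < 1, end_prev > 0, end_prev < 1,
            n_cycles >= 1)
  init <- occupancy_from_prevalence(start_prev, anaemic_shares)
  spec <- trajectory_spec(n_cycles = n_cycles)
  end_prev_at <- function(k) {
    m <- build_transition_matrix(worsening_rates, k * recovery_pattern, arm)
    traj <- simulate_cohort_fractions(init, m, spec)
    prevalence(traj)[n_cycles]
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- end_prev_at(lo) - end_prev  # positive when recovery too weak
  f_hi <- end_prev_at(hi) - end_prev
  if (abs(f_lo) <= tol_prevalence) {
    k <- lo
  } else if (f_lo < 0 || f_hi > 0) {
    stop(sprintf(paste0("target end prevalence %.4f unreachable: bracket ",
                        "[%g, %g] gives prevalences [%.4f, %.4f]"),
                 end_prev, lo, hi, f_hi + end_prev, f_lo + end_prev),
         call. = FALSE)
  } else {
    k <- NA
  }
  iter <- 0L
  if (is.na(k)) {
    while (hi - lo > tol_multiplier) {
      mid <- (lo + hi) / 2
      if (end_prev_at(mid) - end_prev > 0) lo <- mid else hi <- mid
      iter <- iter + 1L
    }
    k <- (lo + hi) / 2
  }
  achieved <- end_prev_at(k)
  if (abs(achieved - end_prev) > tol_prevalence) {
    stop(sprintf("calibration converged to multiplier %.6f but end prevalence %.6f misses target %.4f",
                 k, achieved, end_prev), call. = FALSE)
  }
  list(matrix = build_transition_matrix(worsening_rates, k * recovery_pattern, arm),
       multiplier = k, achieved_prev = achieved, init = init,
       iterations = iter)
}

#' Calibrate the IFC arm's relative risk
#'
#' Finds, by bisection, the relative risk on worsening rates that makes the
#' IFC arm (derived from the non-IFC matrix via [apply_relative_risk()])
#' reach a target end prevalence from its own baseline. End prevalence is
#' strictly increasing in `rr`.
#'
#' @param m_non_ifc The calibrated non-IFC `ifc_transition_matrix`.
#' @param start_prev IFC-arm baseline prevalence.
#' @param end_prev Target IFC-arm prevalence after `n_cycles`.
#' @param n_cycles Number of cycles.
#' @param anaemic_shares Baseline severity mix among anaemic children.
#' @param tol_rr Bisection tolerance on `rr`.
#' @param tol_prevalence Required accuracy of the achieved end prevalence.
#' @return List with `matrix` (IFC arm), `rr`, `achieved_prev`, `init`.
#' @export
calibrate_relative_risk <- function(m_non_ifc, start_prev, end_prev,
                                    n_cycles = 20,
                                    anaemic_shares = c(410, 574, 18) / 1002,
                                    tol_rr = 1e-6, tol_prevalence = 1e-4) {
  validate_transition_matrix(m_non_ifc)
  init <- occupancy_from_prevalence(start_prev, anaemic_shares)
  spec <- trajectory_spec(n_cycles = n_cycles)
  end_prev_at <- function(rr) {
    m <- apply_relative_risk(m_non_ifc, rr, arm = "IFC")
    prevalence(simulate_cohort_fractions(init, m, spec))[n_cycles]
  }
  lo <- 0; hi <- 1
  if (end_prev_at(hi) - end_prev < 0 || end_prev_at(lo) - end_prev > 0) {
    stop("target IFC end prevalence unreachable with rr in [0, 1]",
         call. = FALSE)
  }
  while (hi - lo > tol_rr) {
    mid <- (lo + hi) / 2
    if (end_prev_at(mid) - end_prev < 0) lo <- mid else hi <- mid
  }
  rr <- (lo + hi) / 2
  achieved <- end_prev_at(rr)
  if (abs(achieved - end_prev) > tol_prevalence) {
    stop(sprintf("rr calibration reached %.6f but end prevalence %.6f misses target %.4f",
                 rr, achieved, end_prev), call. = FALSE)
  }
  list(matrix = apply_relative_risk(m_non_ifc, rr, arm = "IFC"),
       rr = rr, achieved_prev = achieved, init = init)
}

#' Read/write a transition matrix as CSV
#'
#' 4x4 matrix with state-labelled header row and first column; an optional
#' `# arm:` comment line records the arm label.
#'
#' @param m An `ifc_transition_matrix`.
#' @param path File path.
#' @export
write_transition_csv <- function(m, path) {
  validate_transition_matrix(m)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# arm: %s", attr(m, "arm")), con)
  df <- data.frame(state = anaemia_states(), unclass(m))
  names(df) <- c("state", anaemia_states())
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transition_csv
#' @export
read_transition_csv <- function(path) {
  first <- readLines(path, n = 1)
  arm <- if (startsWith(first, "# arm:")) trimws(sub("# arm:", "", first)) else NA
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, anaemia_states()])
  validate_transition_matrix(new_transition_matrix(m, arm))
}
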