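# Fixtures built in code: small cohorts and matrices reused across tests.

# Representative in-interval Hb value per state.
hb_for_state <- function(state) {
  c(none = 12, mild = 10.5, moderate = 8.5, severe = 6)[state]
}

# A cohort with exact per-state counts; other fields cycled deterministically.
make_count_cohort <- function(none = 0, mild = 0, moderate = 0, severe = 0,
                              ifc_every = 20L) {
  states <- rep(anaemia_states(), times = c(none, mild, moderate, severe))
  n <- length(states)
  df <- data.frame(
    id = seq_len(n),
    age_band = rep(c("6-<12", "12-<18", "18-<24"), length.out = n),
    sex = rep(c("boy", "girl"), length.out = n),
    wealth_quintile = rep(1:5, length.out = n),
    hb = unname(hb_for_state(states)),
    state = factor(states, levels = anaemia_states()),
    ifc = seq_len(n) %% ifc_every == 0,
    stringsAsFactors = FALSE
  )
  as_ifc_cohort(df, provenance = "test fixture with fixed counts")
}

# A valid full 4-state transition matrix for oracle checks.
make_test_matrix <- function(arm = "non-IFC") {
  build_transition_matrix(worsening_rates = c(0.12, 0.08, 0.02),
                          recovery_rates = c(0.30, 0.20, 0.25),
                          arm = arm)
}

# Random row-stochastic adjacency matrix (for property loops).
random_adjacent_matrix <- function() {
  build_transition_matrix(worsening_rates = stats::runif(3, 0, 0.5),
                          recovery_rates = stats::runif(3, 0, 0.8))
}

# Random occupancy vector on the simplex.
random_occupancy <- function() {
  x <- stats::rexp(4)
  x / sum(x)
}

# Fast config for pipeline tests.
test_config <- function(expand_n = 2000, seed = 42L) {
  default_run_config(expand_n = expand_n, seed = seed)
}
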