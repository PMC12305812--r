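test_that("haemoglobin categorisation follows the WHO cut-offs with half-open intervals", {
  expect_equal(as.character(categorize_anaemia(10.5)), "mild")
  expect_equal(as.character(categorize_anaemia(11.0)), "none")
  expect_equal(as.character(categorize_anaemia(6.9)), "severe")
  expect_equal(as.character(categorize_anaemia(8.0)), "moderate")
  # lower-closed boundaries
  expect_equal(as.character(categorize_anaemia(c(7, 10))),
               c("moderate", "mild"))
  expect_error(categorize_anaemia(0), "positive")
  expect_error(categorize_anaemia(c(10, NA)), "finite")
  expect_error(categorize_anaemia(Inf), "finite")
})

test_that("base cohort sampling respects the spec and its marginals", {
  spec <- base_population_spec()
  cohort <- sample_base_cohort(spec, seed = 1)
  expect_s3_class(cohort, "ifc_cohort")
  expect_equal(nrow(cohort), 1707)
  expect_false(anyDuplicated(cohort$id) > 0)

  # anaemic fraction within the exact binomial 99% CI of 1 - p_none
  # (qbinom(c(.005, .995), 1707, 1002/1707) = 949..1054 anaemic children)
  n_anaemic <- sum(cohort$state != "none")
  expect_gte(n_anaemic, 949)
  expect_lte(n_anaemic, 1054)

  # hb always consistent with state
  expect_equal(as.character(categorize_anaemia(cohort$hb)),
               as.character(cohort$state))
})

test_that("degenerate state distribution yields an all-healthy cohort", {
  spec <- base_population_spec(n_base = 300,
                               p_anaemia_state = c(1, 0, 0, 0))
  cohort <- sample_base_cohort(spec, seed = 99)
  expect_true(all(cohort$state == "none"))
  expect_true(all(cohort$hb >= 11))
})

test_that("cohort sampling is seed-deterministic", {
  spec <- base_population_spec(n_base = 500)
  a <- sample_base_cohort(spec, seed = 7)
  b <- sample_base_cohort(spec, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- sample_base_cohort(spec, seed = 8)
  expect_false(identical(a$hb, c$hb))
})

test_that("population spec validation rejects malformed inputs", {
  expect_error(base_population_spec(p_sex = c(0.6, 0.6)), "sum to 1")
  expect_error(base_population_spec(p_wealth = c(0.5, 0.5, 0.2, -0.1, -0.1)),
               "probabilities")
  expect_error(base_population_spec(hb_sd_by_state = c(none = 1, mild = 0,
                                                       moderate = 1, severe = 1)),
               "positive")
})

test_that("expansion recovers the base marginals and is deterministic", {
  spec <- base_population_spec()
  base <- sample_base_cohort(spec, seed = 3)
  big <- expand_cohort(base, n = 100000, seed = 7)
  expect_equal(nrow(big), 100000)
  expect_false(anyDuplicated(big$id) > 0)

  # every marginal frequency within 3 multinomial SEs of the base frequency
  check_marginal <- function(col) {
    base_tab <- table(base[[col]]) / nrow(base)
    big_tab <- table(factor(big[[col]], levels = names(base_tab))) / nrow(big)
    se <- sqrt(base_tab * (1 - base_tab) / nrow(big))
    expect_true(all(abs(big_tab - base_tab) <= 3 * se),
                label = sprintf("marginal recovery for %s", col))
  }
  for (col in c("state", "sex", "age_band", "wealth_quintile", "ifc")) {
    check_marginal(col)
  }

  expect_identical(as.data.frame(expand_cohort(base, 1000, seed = 5)),
                   as.data.frame(expand_cohort(base, 1000, seed = 5)))
})

test_that("expanding a single-record base copies that record", {
  one <- make_count_cohort(moderate = 1)
  ten <- expand_cohort(one, n = 10, seed = 1)
  expect_equal(nrow(ten), 10)
  expect_true(all(ten$hb == one$hb[1]))
  expect_true(all(ten$state == "moderate"))
  expect_equal(ten$id, 1:10)
})

test_that("cohort summary reproduces printed count/percentage arithmetic", {
  cohort <- make_count_cohort(none = 705, mild = 410, moderate = 574,
                              severe = 18)
  s <- summarize_cohort(cohort)
  tab <- s$table
  state_pct <- function(lvl) {
    tab$pct[tab$variable == "anaemia_state" & tab$level == lvl]
  }
  expect_equal(state_pct("moderate"), 33.63)
  expect_equal(state_pct("severe"), 1.05)
  expect_equal(state_pct("none"), 41.30)
  expect_equal(state_pct("mild"), 24.02)
  expect_equal(s$n_total, 1707)

  healthy <- make_count_cohort(none = 50)
  h <- summarize_cohort(healthy)$table
  expect_true(all(h$pct[h$variable == "anaemia_state" &
                          h$level != "none"] == 0))
})

test_that("cohort CSV round-trips including provenance and byte-identical rewrites", {
  spec <- base_population_spec(n_base = 200)
  cohort <- sample_base_cohort(spec, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back)$hb, as.data.frame(cohort)$hb)
  expect_equal(as.character(back$state), as.character(cohort$state))

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(sample_base_cohort(spec, seed = 11), path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("cohort validation catches inconsistent state/hb and bad fields", {
  good <- make_count_cohort(none = 5, mild = 5)
  bad <- as.data.frame(good)
  bad$state[1] <- "severe"  # hb says none
  expect_error(as_ifc_cohort(bad), "inconsistent")
  dup <- as.data.frame(good)
  dup$id[2] <- dup$id[1]
  expect_error(as_ifc_cohort(dup), "unique")
  expect_error(as_ifc_cohort(good[0, ]), "non-empty")
})
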