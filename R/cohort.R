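#' Specification of the base survey-like population
#'
#' Describes the marginal structure of a national survey sample of children
#' aged 6 to below 24 months: age band, sex, household wealth quintile,
#' anaemia severity, haemoglobin given severity, and the probability of
#' consuming iron-fortified infant cereals (IFC) by sex. Defaults reproduce
#' the marginal frequencies of the 1,707-child base sample the model
#' emulates (e.g. 41.30% not anaemic, 24.02% mild, 33.63% moderate,
#' 1.05% severe; 5.6% of boys and 4.3% of girls consuming IFC).
#'
#' Children under 6 months are excluded (assumed exclusively breastfed), so
#' the three age bands cover 6 to below 24 months only.
#'
#' @param n_base Number of children in the base sample (default 1707).
#' @param p_age_band Probabilities of the age bands 6–<12, 12–<18 and
#'   18–<24 months; must sum to 1.
#' @param p_sex Probabilities of boy and girl; must sum to 1.
#' @param p_wealth Probabilities of wealth quintiles 1 (poorest) to 5
#'   (wealthiest); must sum to 1.
#' @param p_anaemia_state Probabilities of the four severity states
#'   none/mild/moderate/severe; must sum to 1.
#' @param hb_mean_by_state,hb_sd_by_state Named numeric vectors (one entry
#'   per state) giving the mean and SD of haemoglobin (g/dL) within each
#'   state; haemoglobin is drawn from a normal truncated to the state's Hb
#'   interval so state and Hb are always consistent.
#' @param p_ifc_by_sex Named vector `c(boy = , girl = )` of probabilities of
#'   IFC consumption.
#' @param seed Default integer seed carried with the spec.
#' @return Object of class `ifc_population_spec` (a validated list).
#' @seealso [sample_base_cohort()], [expand_cohort()]
#' @export
base_population_spec <- function(n_base = 1707,
                                 p_age_band = c(469, 595, 643) / 1707,
                                 p_sex = c(872, 835) / 1707,
                                 p_wealth = c(299, 323, 368, 403, 314) / 1707,
                                 p_anaemia_state = c(705, 410, 574, 18) / 1707,
                                 hb_mean_by_state = c(none = 12.4, mild = 10.5,
                                                      moderate = 8.5, severe = 6.2),
                                 hb_sd_by_state = c(none = 1.0, mild = 0.5,
                                                    moderate = 0.8, severe = 0.6),
                                 p_ifc_by_sex = c(boy = 0.056, girl = 0.043),
                                 seed = 1L) {
  spec <- structure(
    list(n_base = n_base,
         p_age_band = stats::setNames(p_age_band, age_bands()),
         p_sex = stats::setNames(p_sex, c("boy", "girl")),
         p_wealth = stats::setNames(p_wealth, 1:5),
         p_anaemia_state = stats::setNames(p_anaemia_state, anaemia_states()),
         hb_mean_by_state = hb_mean_by_state[anaemia_states()],
         hb_sd_by_state = hb_sd_by_state[anaemia_states()],
         p_ifc_by_sex = p_ifc_by_sex[c("boy", "girl")],
         seed = as.integer(seed)),
    class = "ifc_population_spec"
  )
  validate_population_spec(spec)
  spec
}

age_bands <- function() c("6-<12", "12-<18", "18-<24")

validate_population_spec <- function(spec) {
  stopifnot(inherits(spec, "ifc_population_spec"))
  if (!is.numeric(spec$n_base) || spec$n_base < 1) {
    stop("`n_base` must be a positive count", call. = FALSE)
  }
  check_simplex <- function(p, what, len) {
    if (length(p) != len || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop(sprintf("`%s` must be %d probabilities in [0, 1]", what, len),
           call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-12) {
      stop(sprintf("`%s` must sum to 1 (got %.15f)", what, sum(p)),
           call. = FALSE)
    }
  }
  check_simplex(spec$p_age_band, "p_age_band", 3)
  check_simplex(spec$p_sex, "p_sex", 2)
  check_simplex(spec$p_wealth, "p_wealth", 5)
  check_simplex(spec$p_anaemia_state, "p_anaemia_state", 4)
  if (any(is.na(spec$hb_mean_by_state)) || any(is.na(spec$hb_sd_by_state))) {
    stop("hb mean/sd must be given for all four states", call. = FALSE)
  }
  if (any(spec$hb_sd_by_state <= 0)) {
    stop("`hb_sd_by_state` must be positive", call. = FALSE)
  }
  if (any(spec$p_ifc_by_sex < 0) || any(spec$p_ifc_by_sex > 1) ||
      any(is.na(spec$p_ifc_by_sex))) {
    stop("`p_ifc_by_sex` must give probabilities for boy and girl",
         call. = FALSE)
  }
  invisible(spec)
}

# Inverse-CDF draw from N(mean, sd) truncated to [lo, hi).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, p_lo, p_hi)
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, lo + 1e-9), hi - 1e-9)
}

new_cohort <- function(df, seed, provenance) {
  structure(df, seed = as.integer(seed), provenance = provenance,
            class = c("ifc_cohort", "data.frame"))
}

#' Coerce and validate a data frame as a cohort
#'
#' A cohort holds one row per child with columns `id` (unique integer),
#' `age_band`, `sex`, `wealth_quintile` (1–5), `hb` (g/dL), `state`
#' (anaemia severity consistent with `hb` under [categorize_anaemia()])
#' and `ifc` (logical intervention-arm flag).
#'
#' @param df Data frame with the cohort columns.
#' @param seed Integer seed recorded as provenance (default `NA`).
#' @param provenance Free-text description of how the cohort was made.
#' @return An `ifc_cohort` object.
#' @export
as_ifc_cohort <- function(df, seed = NA_integer_, provenance = "user-supplied") {
  cohort <- new_cohort(as.data.frame(df), seed, provenance)
  validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  needed <- c("id", "age_band", "sex", "wealth_quintile", "hb", "state", "ifc")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cohort) == 0) stop("cohort must be non-empty", call. = FALSE)
  if (anyDuplicated(cohort$id)) stop("cohort ids must be unique", call. = FALSE)
  if (!all(cohort$age_band %in% age_bands())) {
    stop("unknown age band in cohort", call. = FALSE)
  }
  if (!all(cohort$sex %in% c("boy", "girl"))) {
    stop("sex must be 'boy' or 'girl'", call. = FALSE)
  }
  if (!all(cohort$wealth_quintile %in% 1:5)) {
    stop("wealth_quintile must be in 1..5", call. = FALSE)
  }
  if (any(!is.finite(cohort$hb)) || any(cohort$hb <= 0) || any(cohort$hb >= 25)) {
    stop("hb must lie in (0, 25) g/dL", call. = FALSE)
  }
  implied <- as.character(categorize_anaemia(cohort$hb))
  if (!all(as.character(cohort$state) == implied)) {
    stop("cohort `state` inconsistent with `hb` under categorize_anaemia",
         call. = FALSE)
  }
  if (!is.logical(cohort$ifc)) stop("`ifc` must be logical", call. = FALSE)
  invisible(cohort)
}

#' Draw a synthetic base cohort from marginal frequencies
#'
#' Samples `spec$n_base` children with fields drawn independently from the
#' spec's marginals (the base survey reports no significant associations
#' between them), except that haemoglobin is drawn conditionally on the
#' anaemia state from a truncated normal restricted to the state's Hb
#' interval, so state and Hb are consistent by construction.
#'
#' @param spec A [base_population_spec()].
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   exactly.
#' @return An `ifc_cohort` data frame of `spec$n_base` children.
#' @examples
#' cohort <- sample_base_cohort(base_population_spec(n_base = 200), seed = 1)
#' summarize_cohort(cohort)$hb_mean
#' @export
sample_base_cohort <- function(spec, seed = spec$seed) {
  validate_population_spec(spec)
  set.seed(as.integer(seed))
  n <- spec$n_base
  states <- anaemia_states()
  state <- sample(states, n, replace = TRUE, prob = spec$p_anaemia_state)
  hb <- numeric(n)
  for (s in states) {
    idx <- which(state == s)
    if (length(idx) == 0) next
    b <- state_hb_bounds(s)
    hb[idx] <- rtrunc_norm(length(idx), spec$hb_mean_by_state[[s]],
                           spec$hb_sd_by_state[[s]], b[1], b[2])
  }
  sex <- sample(c("boy", "girl"), n, replace = TRUE, prob = spec$p_sex)
  ifc <- stats::runif(n) < spec$p_ifc_by_sex[sex]
  df <- data.frame(
    id = seq_len(n),
    age_band = sample(age_bands(), n, replace = TRUE, prob = spec$p_age_band),
    sex = sex,
    wealth_quintile = sample(1:5, n, replace = TRUE, prob = spec$p_wealth),
    hb = round(hb, 4),
    state = factor(state, levels = states),
    ifc = unname(ifc),
    stringsAsFactors = FALSE
  )
  cohort <- new_cohort(df, seed, "synthetic base cohort from marginal spec")
  validate_cohort(cohort)
  cohort
}

#' Expand a base cohort into a virtual cohort by resampling
#'
#' Monte-Carlo expansion: draws `n` children with replacement from the base
#' cohort and assigns fresh ids, so every joint category frequency of the
#' expansion converges to the base frequency as `n` grows.
#'
#' @param base An `ifc_cohort` (typically the 1,707-child base sample).
#' @param n Size of the virtual cohort (default 100000).
#' @param seed Integer seed.
#' @return An `ifc_cohort` of `n` children.
#' @export
expand_cohort <- function(base, n = 100000, seed = 1L) {
  validate_cohort(base)
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(base), n, replace = TRUE)
  df <- as.data.frame(base)[idx, , drop = FALSE]
  df$id <- seq_len(n)
  rownames(df) <- NULL
  new_cohort(df, seed,
             sprintf("virtual cohort of %d resampled from base of %d", n, nrow(base)))
}

#' Summarise a cohort as counts and percentages
#'
#' Tabulates anaemia state, sex, age band, wealth quintile and IFC
#' consumption as counts with percentages (two decimals,
#' 100 * count / total), plus the haemoglobin mean and SD.
#'
#' @param cohort An `ifc_cohort`.
#' @return A list with `table` (data frame: variable, level, n, pct),
#'   `hb_mean`, `hb_sd` and `n_total`.
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort)
  n_total <- nrow(cohort)
  one_var <- function(values, levels, variable) {
    counts <- table(factor(values, levels = levels))
    data.frame(variable = variable,
               level = names(counts),
               n = as.integer(counts),
               pct = round(100 * as.integer(counts) / n_total, 2),
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    one_var(cohort$state, anaemia_states(), "anaemia_state"),
    one_var(cohort$sex, c("boy", "girl"), "sex"),
    one_var(cohort$age_band, age_bands(), "age_band"),
    one_var(cohort$wealth_quintile, 1:5, "wealth_quintile"),
    one_var(ifelse(cohort$ifc, "yes", "no"), c("yes", "no"), "ifc")
  )
  list(table = tab,
       hb_mean = mean(cohort$hb),
       hb_sd = stats::sd(cohort$hb),
       n_total = n_total)
}

#' Empirical state occupancy of a cohort
#'
#' Fraction of children in each anaemia severity state, optionally within
#' one arm (`ifc = TRUE` or `FALSE`); used as the baseline occupancy vector
#' for the Markov projection.
#'
#' @param cohort An `ifc_cohort`.
#' @param ifc If not `NULL`, restrict to children with this IFC flag.
#' @return Named numeric 4-vector summing to 1.
#' @export
state_occupancy <- function(cohort, ifc = NULL) {
  validate_cohort(cohort)
  if (!is.null(ifc)) cohort <- cohort[cohort$ifc == ifc, , drop = FALSE]
  if (nrow(cohort) == 0) stop("no children in the requested arm", call. = FALSE)
  counts <- table(factor(cohort$state, levels = anaemia_states()))
  stats::setNames(as.numeric(counts) / sum(counts), anaemia_states())
}

#' Read/write a cohort as CSV
#'
#' Plain UTF-8 CSV with a header row and columns id, age_band, sex,
#' wealth_quintile, hb, state, ifc. Comment lines starting `#` record the
#' seed and provenance so the file can be regenerated exactly.
#'
#' @param cohort An `ifc_cohort`.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a validated `ifc_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# seed: %s", attr(cohort, "seed")),
               sprintf("# provenance: %s", attr(cohort, "provenance"))), con)
  df <- as.data.frame(cohort)
  df$state <- as.character(df$state)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$state <- factor(df$state, levels = anaemia_states())
  df$ifc <- as.logical(df$ifc)
  as_ifc_cohort(df, provenance = sprintf("read from %s", basename(path)))
}
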