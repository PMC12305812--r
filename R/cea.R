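#' Food cost inputs
#'
#' Per-day food costs for children aged 6 to below 24 months: home-based
#' foods cost 0.37 USD per child per day and iron-fortified infant cereals
#' add 0.17 USD per day on top, over an intervention window of up to 18
#' months (6 months to 2 years of age, with 0-6 months exclusively
#' breastfed).
#'
#' @param home_food_per_day USD per day for home-based foods (default 0.37).
#' @param ifc_increment_per_day Additional USD per day for IFC (default 0.17).
#' @param intervention_months Months of food consumption counted (default
#'   18; children starting later consume for 12 or 6 months).
#' @param days_per_month Days per month used in totals (default 30).
#' @return List of class `ifc_cost_inputs`.
#' @export
cost_inputs <- function(home_food_per_day = 0.37, ifc_increment_per_day = 0.17,
                        intervention_months = 18, days_per_month = 30) {
  if (min(home_food_per_day, ifc_increment_per_day, intervention_months,
          days_per_month) < 0) {
    stop("cost inputs must be non-negative", call. = FALSE)
  }
  if (intervention_months > 18) {
    stop("`intervention_months` cannot exceed 18 (6-24-month window)",
         call. = FALSE)
  }
  structure(list(home_food_per_day = home_food_per_day,
                 ifc_increment_per_day = ifc_increment_per_day,
                 intervention_months = intervention_months,
                 days_per_month = days_per_month),
            class = "ifc_cost_inputs")
}

#' Total food cost per child over the intervention window
#'
#' `per_day * intervention_months * days_per_month`, where the per-day cost
#' is home food alone or home food plus the IFC increment. With defaults:
#' 0.37 * 540 = 199.8 USD without IFC and 0.54 * 540 = 291.6 USD with IFC.
#'
#' @param c A [cost_inputs()] object.
#' @param with_ifc Include the IFC increment?
#' @return Total USD per child.
#' @export
total_food_cost <- function(c = cost_inputs(), with_ifc = FALSE) {
  stopifnot(inherits(c, "ifc_cost_inputs"))
  per_day <- c$home_food_per_day +
    if (isTRUE(with_ifc)) c$ifc_increment_per_day else 0
  per_day * c$intervention_months * c$days_per_month
}

#' Incremental cost-effectiveness ratio
#'
#' `ICER = (cost_int - cost_comp) / (eff_int - eff_comp)`. Effects default
#' to burden units (disability days or DALYs, lower is better), so the
#' intervention is "more effective" when its effect value is smaller; set
#' `effect_direction = "benefit"` for effects where larger is better. The
#' cost-effectiveness-plane quadrant is reported so that a negative ratio
#' from "more costly, more effective" is distinguishable from dominance.
#'
#' @param cost_int,cost_comp Costs (USD) of intervention and comparator.
#' @param eff_int,eff_comp Effects of intervention and comparator; must
#'   differ.
#' @param effect_direction `"burden"` (default; lower effect is better) or
#'   `"benefit"`.
#' @return List of class `ifc_icer` with `icer`, `incremental_cost`,
#'   `incremental_effect` (signed so positive = health gained) and
#'   `quadrant`.
#' @examples
#' icer(291, 199.8, 77, 99)  # -4.145 USD per disability day averted
#' @export
icer <- function(cost_int, cost_comp, eff_int, eff_comp,
                 effect_direction = c("burden", "benefit")) {
  effect_direction <- match.arg(effect_direction)
  if (eff_int == eff_comp) {
    stop("effects are equal: the ICER is undefined; compare arms with net_monetary_benefit() instead",
         call. = FALSE)
  }
  d_cost <- cost_int - cost_comp
  d_eff_raw <- eff_int - eff_comp
  gain <- if (effect_direction == "burden") -d_eff_raw else d_eff_raw
  quadrant <- if (d_cost >= 0 && gain > 0) {
    "more costly, more effective"
  } else if (d_cost < 0 && gain > 0) {
    "dominant (less costly, more effective)"
  } else if (d_cost >= 0) {
    "dominated (more costly, less effective)"
  } else {
    "less costly, less effective"
  }
  structure(list(icer = d_cost / d_eff_raw,
                 incremental_cost = d_cost,
                 incremental_effect = gain,
                 quadrant = quadrant),
            class = "ifc_icer")
}

#' Willingness-to-pay threshold
#'
#' Benchmark for judging an ICER, expressed per unit of health gain per
#' day; the default is Egypt's daily GDP per capita of 6.6 USD with a 1x
#' multiplier, following the WHO-CHOICE convention.
#'
#' @param gdp_per_capita_per_day USD (default 6.6).
#' @param multiplier Dimensionless multiplier on the benchmark (default 1).
#' @return List of class `ifc_wtp`.
#' @export
wtp_threshold <- function(gdp_per_capita_per_day = 6.6, multiplier = 1) {
  if (gdp_per_capita_per_day <= 0 || multiplier <= 0) {
    stop("threshold components must be positive", call. = FALSE)
  }
  structure(list(gdp_per_capita_per_day = gdp_per_capita_per_day,
                 multiplier = multiplier),
            class = "ifc_wtp")
}

#' WHO-CHOICE cost-effectiveness classification
#'
#' Compares the ICER magnitude to the GDP-per-capita benchmark: below 1x is
#' highly cost-effective, below 3x is cost-effective, otherwise not
#' cost-effective. The absolute value is used because a negative ICER from
#' the "more costly, more effective" quadrant is interpreted independently
#' of its sign.
#'
#' @param icer_value ICER (USD per unit of health gain), sign ignored.
#' @param t A [wtp_threshold()].
#' @return One of `"highly cost-effective"`, `"cost-effective"`,
#'   `"not cost-effective"`.
#' @export
classify_who_choice <- function(icer_value, t = wtp_threshold()) {
  stopifnot(inherits(t, "ifc_wtp"))
  base <- t$multiplier * t$gdp_per_capita_per_day
  v <- abs(icer_value)
  if (v < base) "highly cost-effective"
  else if (v < 3 * base) "cost-effective"
  else "not cost-effective"
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_effect - delta_cost`; positive NMB means the
#' intervention is acceptable at that willingness-to-pay.
#'
#' @param delta_effect Health gained (e.g. disability days averted).
#' @param delta_cost Incremental cost (USD).
#' @param wtp Willingness-to-pay per unit of health gain (USD, >= 0).
#' @return USD.
#' @export
net_monetary_benefit <- function(delta_effect, delta_cost, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be non-negative", call. = FALSE)
  wtp * delta_effect - delta_cost
}

#' Population-level savings
#'
#' Scales a per-child per-unit saving to the national population (e.g.
#' 1.92 USD per disability day averted times 4.058 million children under
#' two).
#'
#' @param cost_per_unit USD saved per child per unit of health gain.
#' @param population Number of children.
#' @return List with `total_usd` and `millions` (rounded to 2 decimals).
#' @export
population_savings <- function(cost_per_unit, population) {
  if (cost_per_unit < 0 || population < 0) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  total <- cost_per_unit * population
  list(total_usd = total, millions = round(total / 1e6, 2))
}

#' Assemble a full cost-effectiveness result for two arms
#'
#' Combines per-arm costs and burden into incremental results: the
#' headline ICER in USD per disability day averted, the DALY-denominated
#' ICER, the WHO-CHOICE classification and the net monetary benefit at the
#' given threshold.
#'
#' @param burden_ifc,burden_non_ifc `ifc_burden` results per arm.
#' @param costs A [cost_inputs()].
#' @param wtp A [wtp_threshold()].
#' @return List of class `ifc_cea_result`.
#' @export
cea_summary <- function(burden_ifc, burden_non_ifc, costs = cost_inputs(),
                        wtp = wtp_threshold()) {
  cost_ifc <- total_food_cost(costs, with_ifc = TRUE)
  cost_non <- total_food_cost(costs, with_ifc = FALSE)
  diff <- daly_difference(burden_ifc, burden_non_ifc)
  ic <- icer(cost_ifc, cost_non,
             burden_ifc$disability_days, burden_non_ifc$disability_days)
  horizon_years <- burden_ifc$horizon_days / 365
  icer_per_daly <- ic$incremental_cost /
    (burden_ifc$disability_days - burden_non_ifc$disability_days) * 365
  structure(list(
    cost_per_arm = c(ifc = cost_ifc, non_ifc = cost_non),
    effect_per_arm = c(ifc = burden_ifc$disability_days,
                       non_ifc = burden_non_ifc$disability_days),
    daily_daly_per_arm = c(ifc = burden_ifc$daily_daly,
                           non_ifc = burden_non_ifc$daily_daly),
    incremental_cost = ic$incremental_cost,
    days_averted = diff$disability_days_averted,
    daily_daly_averted = diff$daily_daly_averted,
    icer_per_day = ic$icer,
    icer_per_daly = icer_per_daly,
    quadrant = ic$quadrant,
    classification = classify_who_choice(ic$icer, wtp),
    nmb = net_monetary_benefit(diff$disability_days_averted,
                               ic$incremental_cost,
                               wtp$multiplier * wtp$gdp_per_capita_per_day),
    horizon_years = horizon_years),
    class = "ifc_cea_result")
}

#' @export
print.ifc_cea_result <- function(x, ...) {
  cat("Cost-effectiveness result (", x$horizon_years, "-year horizon)\n", sep = "")
  cat(sprintf("  cost/child:        IFC %.2f USD vs non-IFC %.2f USD (delta %.2f)\n",
              x$cost_per_arm[["ifc"]], x$cost_per_arm[["non_ifc"]],
              x$incremental_cost))
  cat(sprintf("  disability days:   IFC %.1f vs non-IFC %.1f (averted %.1f)\n",
              x$effect_per_arm[["ifc"]], x$effect_per_arm[["non_ifc"]],
              x$days_averted))
  cat(sprintf("  DALY/day:          IFC %.4f vs non-IFC %.4f (averted %.4f)\n",
              x$daily_daly_per_arm[["ifc"]], x$daily_daly_per_arm[["non_ifc"]],
              x$daily_daly_averted))
  cat(sprintf("  ICER:              %.3f USD per disability day averted (%s)\n",
              x$icer_per_day, x$quadrant))
  cat(sprintf("  classification:    %s\n", x$classification))
  cat(sprintf("  NMB at threshold:  %.2f USD\n", x$nmb))
  invisible(x)
}
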