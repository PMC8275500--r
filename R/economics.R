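#' Discounting specification
#'
#' @param annual_rate_costs Annual discount rate for costs (default 4%).
#' @param annual_rate_effects Annual discount rate for health effects
#'   (default 1.5%).
#' @param cycle_days Cycle length in days.
#' @return A `discount_spec` object.
#' @export
discount_spec <- function(annual_rate_costs = 0.04,
                          annual_rate_effects = 0.015, cycle_days = 28) {
  if (annual_rate_costs < 0 || annual_rate_effects < 0)
    stop("discount rates must be non-negative")
  structure(list(annual_rate_costs = annual_rate_costs,
                 annual_rate_effects = annual_rate_effects,
                 cycle_days = cycle_days),
            class = "discount_spec")
}

#' Per-cycle discount factor
#'
#' `(1 + r)^(-cycle_index * cycle_days / 365.25)`; cycle 0 is undiscounted.
#'
#' @param spec A [discount_spec()].
#' @param which `"costs"` or `"effects"`.
#' @param cycle_index Non-negative integer cycle index (vectorised).
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(spec, which = c("costs", "effects"), cycle_index) {
  which <- match.arg(which)
  if (any(cycle_index < 0)) stop("cycle_index must be non-negative")
  r <- if (which == "costs") spec$annual_rate_costs else spec$annual_rate_effects
  (1 + r)^(-cycle_index * spec$cycle_days / DAYS_PER_YEAR)
}

#' Utility set of the case study
#'
#' Health-state utilities with the arm-specific utilities for stable disease
#' accompanied by a severe (grade III/IV) adverse event, and the fraction of
#' each arm affected by such an event. All adverse events are assumed to
#' occur at the start of treatment: the AE-blended SD utility applies during
#' the treatment window only.
#'
#' @param u_sd Utility of SD without (or with low-grade) AE.
#' @param u_sd_ae_control,u_sd_ae_intervention Utility of SD with a severe AE,
#'   per arm.
#' @param u_pd Utility of PD.
#' @param u_dead Utility of death (0).
#' @param ae_fraction Named list/vector: fraction of each arm experiencing a
#'   severe AE.
#' @param ae_window_cycles Number of initial cycles over which the AE-blended
#'   utility applies (the treatment window).
#' @return A `utility_set` object.
#' @export
utility_set <- function(u_sd = 0.771, u_sd_ae_control = 0.666,
                        u_sd_ae_intervention = 0.687, u_pd = 0.612,
                        u_dead = 0,
                        ae_fraction = c(control = 0.05, intervention = 0.12),
                        ae_window_cycles = 1) {
  u <- c(u_sd, u_sd_ae_control, u_sd_ae_intervention, u_pd, u_dead)
  if (any(u < 0 | u > 1)) stop("utilities must lie in [0, 1]")
  if (u_dead != 0) stop("the utility of death must be 0")
  structure(list(u_sd = u_sd, u_sd_ae_control = u_sd_ae_control,
                 u_sd_ae_intervention = u_sd_ae_intervention, u_pd = u_pd,
                 u_dead = u_dead, ae_fraction = as.list(ae_fraction),
                 ae_window_cycles = ae_window_cycles),
            class = "utility_set")
}

#' Accumulate discounted QALYs and life-years over a cohort trace
#'
#' Per cycle, the QALY increment is
#' `(occ_sd * u_sd_eff + occ_pd * u_pd) * cycle_years * discount`, where
#' `u_sd_eff` blends the SD utility with the arm's severe-AE utility by the
#' affected fraction during the treatment window. Life-years use utility 1
#' for the alive states and the same (effects) discounting.
#'
#' @param trace A `cohort_trace`.
#' @param utilities A [utility_set()].
#' @param spec A [discount_spec()].
#' @param arm `"control"` or `"intervention"`.
#' @return List with `qalys` and `life_years` (discounted totals per modelled
#'   patient).
#' @export
accumulate_qalys <- function(trace, utilities, spec, arm) {
  arm <- match.arg(arm, c("control", "intervention"))
  u_ae <- switch(arm, control = utilities$u_sd_ae_control,
                 intervention = utilities$u_sd_ae_intervention)
  if (is.null(u_ae) || is.na(u_ae))
    stop("missing severe-AE utility for arm '", arm, "'")
  f <- utilities$ae_fraction[[arm]]
  cyc_years <- attr(trace, "cycle_days") / DAYS_PER_YEAR
  df <- discount_factor(spec, "effects", trace$cycle)
  u_sd_eff <- rep(utilities$u_sd, nrow(trace))
  in_window <- trace$cycle < utilities$ae_window_cycles
  u_sd_eff[in_window] <- (1 - f) * utilities$u_sd + f * u_ae
  qalys <- sum((trace$occ_sd * u_sd_eff + trace$occ_pd * utilities$u_pd) *
                 cyc_years * df)
  ly <- sum((trace$occ_sd + trace$occ_pd) * cyc_years * df)
  list(qalys = qalys, life_years = ly)
}

#' Cost schedule of the case study
#'
#' Unit costs (2019 euros) attached to the cohort trace. The radionuclide
#' treatment consists of four injections at fixed cycles, costed at a quarter
#' of the per-treatment price each, conditional on SD occupancy; treatment
#' costs drop to zero on progression. Somatostatin-analogue maintenance is
#' costed per cycle in SD (60 mg every cycle in the control arm; 30 mg at the
#' injection cycles and monthly after completion in the intervention arm).
#' PD follow-up visits every 6 months are pro-rated per cycle. Indirect
#' unrelated medical costs are age-indexed annual amounts pro-rated per cycle
#' for the alive, plus a one-time end-of-life amount for the newly dead.
#'
#' @param lo_price_initial,lo_price_increased Price per radionuclide treatment
#'   (four injections) under the two price scenarios.
#' @param lo_admin_per_injection Administration cost per injection (day-care
#'   admission with radioprotection).
#' @param lo_injection_cycles Cycles at which the four injections are given.
#' @param olar_cycle_control Drug + administration cost per cycle of 60 mg
#'   octreotide-LAR (control arm, while SD).
#' @param olar_cycle_intervention Same for 30 mg (intervention arm, while SD).
#' @param ae_cost Named vector: one-time severe-AE management cost per arm,
#'   charged at cycle 0.
#' @param followup_visit_cost Cost of a 6-monthly PD follow-up visit
#'   (consultation + blood testing); pro-rated per cycle.
#' @param indirect_by_age data.frame `age`, `annual_cost`, `end_of_life_cost`:
#'   indirect unrelated medical costs.
#' @param currency_year Currency year label.
#' @return A `cost_schedule` object.
#' @export
cost_schedule <- function(lo_price_initial = 16000, lo_price_increased = 90000,
                          lo_admin_per_injection = 1500,
                          lo_injection_cycles = c(0, 2, 4, 6),
                          olar_cycle_control = 3244,
                          olar_cycle_intervention = 982,
                          ae_cost = c(control = 1500, intervention = 2500),
                          followup_visit_cost = 215,
                          indirect_by_age = make_indirect_cost_table(),
                          currency_year = 2019) {
  costs <- c(lo_price_initial, lo_price_increased, lo_admin_per_injection,
             olar_cycle_control, olar_cycle_intervention,
             unlist(ae_cost), followup_visit_cost)
  if (any(costs < 0)) stop("all costs must be non-negative")
  structure(list(lo_price_initial = lo_price_initial,
                 lo_price_increased = lo_price_increased,
                 lo_admin_per_injection = lo_admin_per_injection,
                 lo_injection_cycles = lo_injection_cycles,
                 olar_cycle_control = olar_cycle_control,
                 olar_cycle_intervention = olar_cycle_intervention,
                 ae_cost = as.list(ae_cost),
                 followup_visit_cost = followup_visit_cost,
                 indirect_by_age = indirect_by_age,
                 currency_year = currency_year),
            class = "cost_schedule")
}

#' Accumulate discounted costs over a cohort trace
#'
#' @param trace A `cohort_trace`.
#' @param costs A [cost_schedule()].
#' @param spec A [discount_spec()].
#' @param arm `"control"` or `"intervention"`.
#' @param price_scenario `"initial"` or `"increased"` (required for the
#'   intervention arm).
#' @param indirect_scale Multiplier on the indirect-cost table (sensitivity
#'   analyses; 0 removes indirect costs).
#' @return Total discounted cost (euros per modelled patient).
#' @export
accumulate_costs <- function(trace, costs, spec, arm,
                             price_scenario = NULL, indirect_scale = 1) {
  arm <- match.arg(arm, c("control", "intervention"))
  cd <- attr(trace, "cycle_days")
  df <- discount_factor(spec, "costs", trace$cycle)
  cyc_years <- cd / DAYS_PER_YEAR
  alive <- trace$occ_sd + trace$occ_pd
  total <- 0

  if (arm == "intervention") {
    if (is.null(price_scenario))
      stop("price_scenario must be set ('initial' or 'increased') for the ",
           "intervention arm")
    price_scenario <- match.arg(price_scenario, c("initial", "increased"))
    price <- switch(price_scenario, initial = costs$lo_price_initial,
                    increased = costs$lo_price_increased)
    inj <- trace$cycle %in% costs$lo_injection_cycles
    per_inj <- price / length(costs$lo_injection_cycles) +
      costs$lo_admin_per_injection
    total <- total + sum(per_inj * trace$occ_sd[inj] * df[inj])
    # 30 mg O-LAR at injection cycles, then monthly after completion
    olar_on <- inj | trace$cycle > max(costs$lo_injection_cycles)
    total <- total + sum(costs$olar_cycle_intervention *
                           trace$occ_sd[olar_on] * df[olar_on])
  } else {
    total <- total + sum(costs$olar_cycle_control * trace$occ_sd * df)
  }

  # PD follow-up: 6-monthly visit pro-rated per cycle
  cycles_per_half_year <- (DAYS_PER_YEAR / 2) / cd
  total <- total + sum(costs$followup_visit_cost / cycles_per_half_year *
                         trace$occ_pd * df)

  # indirect unrelated medical costs: annual by age, pro-rated; end-of-life
  tab <- costs$indirect_by_age
  ages <- pmin(floor(trace$age), max(tab$age))
  idx <- match(ages, tab$age)
  if (anyNA(idx))
    stop("indirect-cost table does not cover age ", min(ages[is.na(idx)]))
  total <- total + indirect_scale *
    (sum(tab$annual_cost[idx] * cyc_years * alive * df) +
       sum(tab$end_of_life_cost[idx] * trace$new_deaths * df))

  total + costs$ae_cost[[arm]]
}

#' Outcome totals of one strategy run
#'
#' @param strategy Strategy label.
#' @param cost Total discounted cost (euros).
#' @param qalys Total discounted QALYs.
#' @param life_years Total discounted life-years.
#' @param price_scenario Price scenario label (or NA).
#' @return An `outcome_totals` object.
#' @export
outcome_totals <- function(strategy, cost, qalys, life_years,
                           price_scenario = NA_character_) {
  if (cost < 0 || qalys < 0 || life_years < 0)
    stop("totals must be non-negative")
  if (qalys > life_years + 1e-9)
    stop("QALYs cannot exceed life-years")
  structure(list(strategy = strategy, cost = cost, qalys = qalys,
                 life_years = life_years, price_scenario = price_scenario),
            class = "outcome_totals")
}

#' @export
print.outcome_totals <- function(x, ...) {
  cat(sprintf("%s%s: cost %s, %.2f QALYs, %.2f LYG\n", x$strategy,
              if (!is.na(x$price_scenario)) paste0(" (", x$price_scenario,
                                                   " price)") else "",
              format(round(x$cost), big.mark = ","), x$qalys, x$life_years))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' `(cost_a - cost_b) / (effect_a - effect_b)`, with the reporting value
#' rounded to the nearest hundred euros. Internal comparisons should use the
#' unrounded value. Quadrants with non-positive incremental effect are
#' flagged as dominance cases rather than reported as a ratio.
#'
#' @param a,b [outcome_totals()] of the strategy of interest (`a`) and the
#'   comparator (`b`).
#' @param effect `"qaly"` or `"ly"`.
#' @return List with `value` (unrounded), `rounded` (nearest hundred),
#'   `delta_cost`, `delta_effect`, and `dominance` (`"none"`, `"dominant"`,
#'   `"dominated"` or `"undefined"`).
#' @export
icer <- function(a, b, effect = c("qaly", "ly")) {
  effect <- match.arg(effect)
  dc <- a$cost - b$cost
  de <- switch(effect, qaly = a$qalys - b$qalys,
               ly = a$life_years - b$life_years)
  if (de == 0) {
    dom <- if (dc < 0) "dominant" else if (dc > 0) "dominated" else "undefined"
    return(list(value = NA_real_, rounded = NA_real_, delta_cost = dc,
                delta_effect = de, dominance = dom))
  }
  dom <- if (de > 0 && dc <= 0) "dominant"
  else if (de < 0 && dc >= 0) "dominated"
  else "none"
  v <- dc / de
  list(value = v, rounded = round(v / 100) * 100, delta_cost = dc,
       delta_effect = de, dominance = dom)
}

#' Net monetary benefit
#'
#' `wtp * (qalys_a - qalys_b) - (cost_a - cost_b)`.
#'
#' @inheritParams icer
#' @param wtp Willingness to pay (euros per QALY), non-negative.
#' @return Net monetary benefit in euros.
#' @export
net_monetary_benefit <- function(a, b, wtp) {
  if (wtp < 0) stop("willingness to pay must be non-negative")
  wtp * (a$qalys - b$qalys) - (a$cost - b$cost)
}

#' Proportional shortfall and willingness-to-pay class
#'
#' The proportional shortfall is the fraction of the remaining
#' quality-adjusted life expectancy of the age/sex-matched healthy population
#' that is lost to the disease:
#' `(QALE_healthy - QALY_disease) / QALE_healthy`, clamped to `[0, 1]`. In
#' the Dutch reimbursement framework the shortfall maps to a reference
#' willingness-to-pay class of 20,000, 50,000 or 80,000 euros per QALY.
#'
#' @param disease_qalys Expected remaining QALYs with the disease (under the
#'   comparator strategy).
#' @param remaining_qale_healthy Remaining quality-adjusted life expectancy
#'   without the disease.
#' @param class_bounds Shortfall boundaries of the three classes.
#' @param thresholds WTP value of each class (euros per QALY).
#' @return List with `shortfall` and `wtp` (the applicable threshold).
#' @export
#' @examples
#' proportional_shortfall(1.79, 18.9)
proportional_shortfall <- function(disease_qalys, remaining_qale_healthy,
                                   class_bounds = c(0.10, 0.41, 0.71),
                                   thresholds = c(20000, 50000, 80000)) {
  if (disease_qalys < 0 || remaining_qale_healthy <= 0)
    stop("inputs must be positive (healthy QALE) and non-negative (QALYs)")
  s <- (remaining_qale_healthy - disease_qalys) / remaining_qale_healthy
  s <- min(max(s, 0), 1)
  cls <- findInterval(s, class_bounds)  # 0 = below lowest class
  wtp <- thresholds[max(cls, 1)]
  list(shortfall = s, wtp = wtp)
}
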