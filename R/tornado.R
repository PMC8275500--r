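#' Default one-way (tornado) analysis parameter set
#'
#' Parameters (or joint groups) varied one at a time between their bounds:
#' the SD and PD utilities at their published ranges, both severe-AE
#' utilities (moved jointly), the overall-survival and progression
#' probabilities (all affected transition probabilities scaled jointly over
#' the 80-120% default interval), the medication, AE-management, follow-up
#' and indirect costs, and the two discount rates (0 to 4%).
#'
#' @param config A `model_config`.
#' @return Named list of [parameter_spec()]s.
#' @export
default_tornado_specs <- function(config) {
  u <- config$utilities
  uc <- config$fixture$utility_ci
  list(
    parameter_spec("u_sd", u$u_sd, "fixed", uc$u_sd[1], uc$u_sd[2],
                   label = "utility SD"),
    parameter_spec("u_pd", u$u_pd, "fixed", uc$u_pd[1], uc$u_pd[2],
                   label = "utility PD"),
    parameter_spec(c("u_sd_ae_control", "u_sd_ae_intervention"),
                   c(u$u_sd_ae_control, u$u_sd_ae_intervention), "fixed",
                   c(uc$u_sd_ae_control[1], uc$u_sd_ae_intervention[1]),
                   c(uc$u_sd_ae_control[2], uc$u_sd_ae_intervention[2]),
                   label = "utilities adverse events"),
    parameter_spec("os_probability", 1, "fixed", 0.8, 1.2,
                   label = "overall survival probability"),
    parameter_spec("pfs_probability", 1, "fixed", 0.8, 1.2,
                   label = "progression probability"),
    parameter_spec(c("cost_olar_control", "cost_olar_intervention"),
                   c(config$costs$olar_cycle_control,
                     config$costs$olar_cycle_intervention), "fixed",
                   0.8 * c(config$costs$olar_cycle_control,
                           config$costs$olar_cycle_intervention),
                   1.2 * c(config$costs$olar_cycle_control,
                           config$costs$olar_cycle_intervention),
                   label = "octreotide-LAR costs"),
    parameter_spec(c("cost_ae_control", "cost_ae_intervention"),
                   c(config$costs$ae_cost$control,
                     config$costs$ae_cost$intervention), "fixed",
                   0.8 * c(config$costs$ae_cost$control,
                           config$costs$ae_cost$intervention),
                   1.2 * c(config$costs$ae_cost$control,
                           config$costs$ae_cost$intervention),
                   label = "adverse-event costs"),
    parameter_spec("cost_followup", config$costs$followup_visit_cost, "fixed",
                   label = "follow-up costs"),
    parameter_spec("cost_indirect_scale", 1, "fixed", 0.8, 1.2,
                   label = "indirect medical costs"),
    parameter_spec("discount_costs", config$discount$annual_rate_costs,
                   "fixed", 0, 0.04, label = "discount rate costs"),
    parameter_spec("discount_effects", config$discount$annual_rate_effects,
                   "fixed", 0, 0.04, label = "discount rate effects"))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter (or joint group) is set to its lower bound and then its
#' upper bound, all others held at base case, and the deterministic ICER per
#' QALY is recomputed. Entries are sorted by bar width (absolute difference
#' of the two ICERs) in descending order. Bounds producing a dominance
#' quadrant are flagged in the `dominance` column rather than dropped.
#'
#' @param config A `model_config`.
#' @param specs List of [parameter_spec()]s; default
#'   [default_tornado_specs()].
#' @param price_scenario Price scenario of the analysed ICER.
#' @return data.frame with columns `parameter`, `icer_low`, `icer_high`
#'   (euros/QALY, rounded to hundreds), `icer_base`, `width`, `dominance`.
#' @export
tornado <- function(config, specs = default_tornado_specs(config),
                    price_scenario = config$price_scenario) {
  base <- run_deterministic(config, price_scenario)
  base_icer <- base$icer_qaly$rounded
  one <- function(spec, side) {
    cfg <- config
    v <- if (side == "lower") spec$lower else spec$upper
    for (j in seq_along(spec$name))
      cfg <- apply_parameter(cfg, spec$name[j], v[j])
    run_deterministic(cfg, price_scenario)$icer_qaly
  }
  rows <- lapply(specs, function(spec) {
    lo <- one(spec, "lower")
    hi <- one(spec, "upper")
    dom <- c(lo$dominance, hi$dominance)
    data.frame(parameter = spec$label,
               icer_low = lo$rounded, icer_high = hi$rounded,
               icer_base = base_icer,
               width = abs(hi$rounded - lo$rounded),
               dominance = paste(unique(dom[dom != "none"]), collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  out
}

#' Write tornado results to CSV
#'
#' @param t A data.frame from [tornado()].
#' @param file Output path.
#' @return `t`, invisibly.
#' @export
write_tornado <- function(t, file) {
  utils::write.csv(t, file, row.names = FALSE)
  invisible(t)
}
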