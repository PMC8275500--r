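.scenario_names <- c("base", "equal_discount_4", "no_discount",
                     "no_extrapolation", "no_indirect_costs",
                     "general_population_survival")

#' Apply a named scenario to a configuration
#'
#' Each scenario is a single documented configuration mutation:
#' * `equal_discount_4` — both discount rates set to 4% per year;
#' * `no_discount` — both discount rates set to 0;
#' * `no_extrapolation` — disease progression switched off beyond the
#'   25-month trial follow-up (the progression probability was extrapolated
#'   beyond that point in the base case);
#' * `no_indirect_costs` — indirect unrelated medical costs (annual and
#'   end-of-life) removed;
#' * `general_population_survival` — the life-table background mortality is
#'   applied as a cyclewise maximum from cycle 0 instead of the permanent
#'   switch at first crossing;
#' * `base` — no change.
#'
#' @param config A `model_config`.
#' @param scenario Scenario name.
#' @return The mutated configuration.
#' @export
apply_scenario <- function(config, scenario) {
  if (!scenario %in% .scenario_names)
    stop("unknown scenario '", scenario, "'; valid names: ",
         paste(.scenario_names, collapse = ", "))
  switch(scenario,
    base = config,
    equal_discount_4 = {
      config$discount$annual_rate_costs <- 0.04
      config$discount$annual_rate_effects <- 0.04
      config
    },
    no_discount = {
      config$discount$annual_rate_costs <- 0
      config$discount$annual_rate_effects <- 0
      config
    },
    no_extrapolation = {
      config$scenario$pfs_stop_month <- 25
      config
    },
    no_indirect_costs = {
      config$scenario$indirect_scale <- 0
      config
    },
    general_population_survival = {
      config$scenario$per_cycle_max <- TRUE
      config
    })
}

#' Run a named scenario
#'
#' Applies exactly one documented configuration mutation (see
#' [apply_scenario()]) and reruns the deterministic model.
#'
#' @param config A `model_config`.
#' @param scenario Scenario name.
#' @param price_scenario Price scenario (defaults to the config's).
#' @return As [run_deterministic()], with the scenario name attached.
#' @export
run_scenario <- function(config, scenario,
                         price_scenario = config$price_scenario) {
  res <- run_deterministic(apply_scenario(config, scenario), price_scenario)
  res$scenario <- scenario
  res
}
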