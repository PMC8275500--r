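.config_fields <- c("cycle_days", "cohort_size", "start_age", "horizon_years",
                    "absorb_threshold", "transition_source", "fixture",
                    "utilities", "costs", "discount", "wtp", "price_scenario",
                    "psa", "scenario")

#' Assemble the full model configuration for the case study
#'
#' Wires the published parameter fixture, the bundled synthetic life table,
#' the synthetic indirect-cost table and the cost structure into a complete,
#' validated model configuration, ready for [run_deterministic()],
#' [run_psa()], [tornado()] or [run_scenario()].
#'
#' @param price_scenario `"initial"` (16,000 euros per treatment) or
#'   `"increased"` (90,000 euros).
#' @param fixture A [case_study_fixture()].
#' @param costs A [cost_schedule()].
#' @param utilities A [utility_set()].
#' @param psa_n,psa_seed Defaults for the probabilistic sensitivity analysis.
#' @return A validated `model_config` object.
#' @export
#' @examples
#' cfg <- make_case_config("increased")
#' cfg$wtp
make_case_config <- function(price_scenario = c("increased", "initial"),
                             fixture = case_study_fixture(),
                             costs = cost_schedule(),
                             utilities = utility_set(),
                             psa_n = 10000, psa_seed = 1) {
  price_scenario <- match.arg(price_scenario)
  cfg <- structure(list(
    cycle_days = fixture$cycle_days,
    cohort_size = fixture$cohort_size,
    start_age = fixture$start_age,
    horizon_years = 60,
    absorb_threshold = 0.99,
    transition_source = "table",
    fixture = fixture,
    utilities = utilities,
    costs = costs,
    discount = discount_spec(fixture$discount_rates[["costs"]],
                             fixture$discount_rates[["effects"]],
                             fixture$cycle_days),
    wtp = fixture$wtp,
    price_scenario = price_scenario,
    psa = list(n = psa_n, seed = psa_seed),
    scenario = list(per_cycle_max = FALSE, pfs_stop_month = Inf,
                    indirect_scale = 1)),
    class = "model_config")
  validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks every constraint and reports all violations at once, not just the
#' first. Unknown top-level keys are rejected.
#'
#' @param config A `model_config`.
#' @return `config`, invisibly; errors with the full list of problems
#'   otherwise.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))
  unknown <- setdiff(names(config), .config_fields)
  if (length(unknown))
    note("unknown config keys: %s", paste(unknown, collapse = ", "))
  missing <- setdiff(.config_fields, names(config))
  if (length(missing))
    note("missing config keys: %s", paste(missing, collapse = ", "))
  num_pos <- function(field) {
    v <- config[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || v <= 0)
      note("field '%s' must be a positive number (got %s)", field,
           deparse(config[[field]]))
  }
  for (f in c("cycle_days", "cohort_size", "start_age", "horizon_years",
              "wtp")) num_pos(f)
  if (!is.null(config$absorb_threshold) &&
      (config$absorb_threshold <= 0 || config$absorb_threshold >= 1))
    note("field 'absorb_threshold' must lie in (0, 1)")
  if (!is.null(config$transition_source) &&
      !config$transition_source %in% c("table", "curves"))
    note("field 'transition_source' must be 'table' or 'curves'")
  if (!is.null(config$price_scenario) &&
      !config$price_scenario %in% c("initial", "increased"))
    note("field 'price_scenario' must be 'initial' or 'increased'")
  u <- config$utilities
  if (!is.null(u)) {
    for (f in c("u_sd", "u_sd_ae_control", "u_sd_ae_intervention", "u_pd")) {
      if (is.null(u[[f]]) || u[[f]] < 0 || u[[f]] > 1)
        note("utility '%s' = %s violates the [0, 1] constraint", f,
             deparse(u[[f]]))
    }
  }
  fx <- config$fixture
  if (!is.null(fx)) {
    for (arm in c("control", "intervention")) {
      tr <- fx$transitions[[arm]]
      if (is.null(tr)) { note("fixture lacks transitions for '%s'", arm); next }
      for (f in names(tr))
        if (tr[[f]] < 0 || tr[[f]] >= 1)
          note("fixture transition %s/%s = %s outside [0, 1)", arm, f,
               deparse(tr[[f]]))
    }
    if (is.null(fx$os_profile$shape) || fx$os_profile$shape <= 0 ||
        is.null(fx$os_profile$rate) || fx$os_profile$rate <= 0)
      note("fixture os_profile shape/rate must be positive")
  }
  if (!is.null(config$psa) &&
      (!is.numeric(config$psa$n) || config$psa$n < 1))
    note("psa$n must be a positive integer")
  if (length(problems))
    stop("invalid model configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(config)
}

#' Evaluate one strategy deterministically
#'
#' Builds the strategy's transition schedule, runs the cohort and accumulates
#' discounted costs, QALYs and life-years.
#'
#' @param config A `model_config`.
#' @param strategy `"control"` or `"intervention"`.
#' @param price_scenario Price scenario (defaults to the config's).
#' @return An [outcome_totals()]; the trace is attached as attribute
#'   `"trace"`.
#' @export
evaluate_strategy <- function(config, strategy,
                              price_scenario = config$price_scenario) {
  strategy <- match.arg(strategy, c("control", "intervention"))
  n_cycles <- ceiling(config$horizon_years * DAYS_PER_YEAR / config$cycle_days)
  sched <- schedule_from_table(config$fixture, strategy, n_cycles,
                               per_cycle_max = config$scenario$per_cycle_max,
                               pfs_stop_month = config$scenario$pfs_stop_month)
  trace <- run_cohort(sched, start = c(1, 0, 0),
                      start_age = config$start_age,
                      absorb_threshold = config$absorb_threshold)
  eff <- accumulate_qalys(trace, config$utilities, config$discount, strategy)
  cost <- accumulate_costs(trace, config$costs, config$discount, strategy,
                           price_scenario = if (strategy == "intervention")
                             price_scenario else NULL,
                           indirect_scale = config$scenario$indirect_scale)
  out <- outcome_totals(strategy, cost, eff$qalys, eff$life_years,
                        if (strategy == "intervention") price_scenario
                        else NA_character_)
  attr(out, "trace") <- trace
  out
}

#' Run the deterministic base-case analysis
#'
#' Evaluates both strategies and computes the incremental cost-effectiveness
#' ratios per QALY and per life-year.
#'
#' @param config A `model_config`.
#' @param price_scenario Price scenario (defaults to the config's).
#' @return List with `control` and `intervention` [outcome_totals()],
#'   `icer_qaly` and `icer_ly` (see [icer()]), and `nmb` at the config's
#'   willingness-to-pay threshold.
#' @export
run_deterministic <- function(config, price_scenario = config$price_scenario) {
  ctrl <- evaluate_strategy(config, "control")
  int <- evaluate_strategy(config, "intervention", price_scenario)
  list(control = ctrl, intervention = int,
       icer_qaly = icer(int, ctrl, "qaly"),
       icer_ly = icer(int, ctrl, "ly"),
       nmb = net_monetary_benefit(int, ctrl, config$wtp))
}

#' Run the full reproducible pipeline
#'
#' Runs both strategies under both price scenarios, producing a results table
#' shaped like the published deterministic analysis (costs, QALYs, LYG and
#' both ICERs per price scenario, costs and ICERs rounded to hundreds), and
#' optionally writes the table, the cohort traces and a run manifest.
#'
#' @param config A `model_config`.
#' @param out_dir Optional output directory for `results.csv`,
#'   `trace_<strategy>.csv` and `manifest.yaml`.
#' @return List with `table` (data.frame), `runs` (per-scenario
#'   [run_deterministic()] results) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  validate_config(config)
  runs <- list(initial = run_deterministic(config, "initial"),
               increased = run_deterministic(config, "increased"))
  ctrl <- runs$initial$control
  rows <- list(data.frame(strategy = "control", price_scenario = NA,
                          cost = round(ctrl$cost / 100) * 100,
                          qaly = ctrl$qalys, lyg = ctrl$life_years,
                          icer_qaly = NA, icer_ly = NA))
  for (sc in names(runs)) {
    int <- runs[[sc]]$intervention
    rows <- c(rows, list(data.frame(
      strategy = "intervention", price_scenario = sc,
      cost = round(int$cost / 100) * 100,
      qaly = int$qalys, lyg = int$life_years,
      icer_qaly = runs[[sc]]$icer_qaly$rounded,
      icer_ly = runs[[sc]]$icer_ly$rounded)))
  }
  tab <- do.call(rbind, rows)
  manifest <- list(
    package = "ceanet",
    version = as.character(utils::packageVersion("ceanet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = config_hash(config),
    price_scenario = config$price_scenario,
    psa_seed = config$psa$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "results.csv"), row.names = FALSE)
    write_trace(attr(runs$increased$control, "trace"),
                file.path(out_dir, "trace_control.csv"))
    write_trace(attr(runs$increased$intervention, "trace"),
                file.path(out_dir, "trace_intervention.csv"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(table = tab, runs = runs, manifest = manifest)
}

#' Stable hash of a model configuration
#'
#' @param config A `model_config`.
#' @return A hex digest string.
#' @export
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, digits.d = 12,
                                              vec.len = 1e6)),
             collapse = "\n")
  # rolling polynomial hash over the serialized text; stable across sessions
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Load a model configuration from a YAML file
#'
#' Reads and validates a configuration; all validation failures are reported
#' together. The life table and indirect-cost table may be inlined (columns
#' as lists) or referenced by CSV path relative to the config file.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `model_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve_table <- function(x, reader) {
    if (is.character(x) && length(x) == 1) {
      f <- if (file.exists(x)) x else file.path(base, x)
      if (!file.exists(f)) stop("referenced file not found: ", x)
      reader(f)
    } else as.data.frame(lapply(x, unlist))
  }
  lt <- resolve_table(raw$life_table, read_life_table)
  if (!inherits(lt, "life_table")) class(lt) <- c("life_table", "data.frame")
  ind <- resolve_table(raw$indirect_costs, read_indirect_cost_table)
  fixture <- case_study_fixture(os_profile = raw$os_profile[c("shape", "rate")],
                                life_table = lt)
  fx_over <- raw$fixture
  if (!is.null(fx_over))
    for (nm in names(fx_over)) fixture[[nm]] <- fx_over[[nm]]
  u <- raw$utilities
  ut <- do.call(utility_set, c(
    u[intersect(names(u), names(formals(utility_set)))]))
  co <- raw$costs
  co$indirect_by_age <- ind
  cs <- do.call(cost_schedule, co[intersect(names(co),
                                            names(formals(cost_schedule)))])
  make_case_config(price_scenario = raw$price_scenario %||% "increased",
                   fixture = fixture, costs = cs, utilities = ut,
                   psa_n = raw$psa$n %||% 10000,
                   psa_seed = raw$psa$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model configuration to YAML
#'
#' Serializes the tunable sections of a configuration (utilities, costs,
#' price scenario, survival time profile, PSA settings) with the life table
#' and indirect-cost table inlined, in the dialect read by [load_config()].
#'
#' @param config A `model_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  u <- config$utilities
  co <- config$costs
  out <- list(
    price_scenario = config$price_scenario,
    os_profile = list(shape = config$fixture$os_profile$shape,
                      rate = config$fixture$os_profile$rate),
    utilities = list(u_sd = u$u_sd, u_sd_ae_control = u$u_sd_ae_control,
                     u_sd_ae_intervention = u$u_sd_ae_intervention,
                     u_pd = u$u_pd,
                     ae_fraction = u$ae_fraction,
                     ae_window_cycles = u$ae_window_cycles),
    costs = list(lo_price_initial = co$lo_price_initial,
                 lo_price_increased = co$lo_price_increased,
                 lo_admin_per_injection = co$lo_admin_per_injection,
                 lo_injection_cycles = co$lo_injection_cycles,
                 olar_cycle_control = co$olar_cycle_control,
                 olar_cycle_intervention = co$olar_cycle_intervention,
                 ae_cost = co$ae_cost,
                 followup_visit_cost = co$followup_visit_cost),
    psa = config$psa,
    life_table = as.list(as.data.frame(config$fixture$life_table)),
    indirect_costs = as.list(co$indirect_by_age))
  yaml::write_yaml(out, path)
  invisible(path)
}
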