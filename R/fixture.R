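#' Indirect unrelated medical costs by age (synthetic)
#'
#' Emulates the structure of the Dutch PAID tool output: mean annual
#' healthcare costs unrelated to the disease under study ("other stages"),
#' rising with age, plus a one-time end-of-life amount, per age. The level
#' parameters are calibrated (see the package vignette); the age gradient is
#' a fixed exponential ramp.
#'
#' @param base_annual Annual cost at `min_age` (euros).
#' @param growth Exponential age gradient (per year).
#' @param end_of_life End-of-life cost (euros, constant over age).
#' @param min_age,max_age Tabulated age span.
#' @return data.frame with columns `age`, `annual_cost`, `end_of_life_cost`.
#' @export
make_indirect_cost_table <- function(base_annual = 3500, growth = 0.035,
                                     end_of_life = 25000,
                                     min_age = 50, max_age = 110) {
  ages <- min_age:max_age
  data.frame(age = ages,
             annual_cost = base_annual * exp(growth * (ages - 63)),
             end_of_life_cost = rep(end_of_life, length(ages)))
}

#' Read an indirect-cost table from CSV
#'
#' @param file CSV with columns `age`, `annual_cost`, `end_of_life_cost`.
#' @return The validated data.frame.
#' @export
read_indirect_cost_table <- function(file) {
  d <- utils::read.csv(file)
  need <- c("age", "annual_cost", "end_of_life_cost")
  if (!all(need %in% names(d)))
    stop("indirect-cost table must have columns ", paste(need, collapse = ","))
  if (any(d$annual_cost < 0 | d$end_of_life_cost < 0))
    stop("indirect costs must be non-negative")
  d
}

#' Case-study parameter fixture
#'
#' All published parameters of the case study, stored verbatim: per-cycle
#' transition probabilities of both arms with their intervals, hazard ratios,
#' health-state utilities with their ranges, cohort constants (1,000 patients
#' aged 63, 28-day cycles), the two treatment prices, discount rates and the
#' willingness-to-pay threshold. The time profile of the death probabilities
#' (a gamma overall-survival hazard shape) is calibrated, not published; its
#' frozen parameters are documented in the vignette.
#'
#' @param os_profile List `shape`, `rate` of the gamma overall-survival time
#'   profile (months); defaults are the package's calibrated values.
#' @param life_table Life table used for the background-mortality override.
#' @return A `case_study_fixture` object.
#' @export
case_study_fixture <- function(os_profile = list(shape = 1.127, rate = 0.002),
                               life_table = make_life_table()) {
  table1 <- data.frame(
    parameter = c("hr_pfs", "hr_os", "hr_sd_vs_pd",
                  "p_sd_pd_control", "p_sd_pd_intervention",
                  "p_sd_d_control", "p_sd_d_intervention",
                  "p_pd_d_control", "p_pd_d_intervention",
                  "u_sd", "u_sd_ae_control", "u_sd_ae_intervention",
                  "u_pd", "u_dead"),
    value = c("0.21", "0.54", "0.44",
              "0.0854", "0.0183", "0.0095", "0.0073", "0.0216", "0.0116",
              "0.771", "0.666", "0.687", "0.612", "0.000"),
    interval = c("0.14-0.33", "", "0.24-0.79",
                 "", "0.0119-0.0283", "", "0.0059-0.0088", "", "0.0093-0.0139",
                 "0.509-0.818", "0.619-0.709", "0.642-0.730", "0.564-0.659",
                 "0.000-0.000"),
    stringsAsFactors = FALSE)
  structure(list(
    table1 = table1,
    transitions = list(
      control = list(sd_pd = 0.0854, sd_d = 0.0095, pd_d = 0.0216),
      intervention = list(sd_pd = 0.0183, sd_d = 0.0073, pd_d = 0.0116)),
    transition_ci = list(
      intervention = list(sd_pd = c(0.0119, 0.0283),
                          sd_d = c(0.0059, 0.0088),
                          pd_d = c(0.0093, 0.0139))),
    hazard_ratios = hazard_ratio_set(
      hr_pfs = 0.21, hr_os = 0.54, hr_sd_vs_pd = 0.44,
      ci = list(hr_pfs = c(0.14, 0.33), hr_sd_vs_pd = c(0.24, 0.79))),
    utility_ci = list(u_sd = c(0.509, 0.818),
                      u_sd_ae_control = c(0.619, 0.709),
                      u_sd_ae_intervention = c(0.642, 0.730),
                      u_pd = c(0.564, 0.659)),
    cycle_days = 28,
    cohort_size = 1000,
    start_age = 63,
    male_fraction = list(control = 0.47, intervention = 0.54),
    prices = c(initial = 16000, increased = 90000),
    discount_rates = c(costs = 0.04, effects = 0.015),
    wtp = 80000,
    os_profile = c(os_profile, list(source = "calibrated")),
    life_table = life_table),
    class = "case_study_fixture")
}

#' Simulation specification for synthetic digitized-KM data
#'
#' @param family,params True survival family and parameters (time in months).
#' @param n Number of patients (>= 2).
#' @param censor_at Administrative censoring time (months; `Inf` for none).
#' @param grid Number of digitized curve points (>= 10).
#' @param risk_times Times of the emitted risk-table rows; defaults to 7
#'   evenly spaced times over the follow-up.
#' @param seed RNG seed.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(family, params, n = 113, censor_at = 40, grid = 60,
                     risk_times = NULL, seed = 1) {
  if (n < 2) stop("n must be at least 2")
  if (grid < 10) stop("digitization grid must have at least 10 points")
  parametric_survival(family, params)  # validates family/params
  structure(list(family = family, params = params, n = n,
                 censor_at = censor_at, grid = grid,
                 risk_times = risk_times, seed = seed),
            class = "sim_spec")
}

#' Simulate a digitized Kaplan-Meier curve from known hazards
#'
#' Draws event times from the specified family, applies administrative
#' censoring, computes the Kaplan-Meier estimator, samples it on an even
#' digitization grid, and tabulates a consistent numbers-at-risk table — the
#' kind of input a plot digitizer would produce from a published figure, but
#' with the generating parameters known, enabling parameter-recovery testing
#' of the reconstruction-and-fitting pipeline.
#'
#' @param spec A [sim_spec()].
#' @return List with `km` (a [digitized_km()]), `true` (the generating
#'   [parametric_survival()]), `ipd` (the underlying simulated records) and
#'   `n_events`.
#' @export
simulate_km <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  true <- parametric_survival(spec$family, spec$params)
  set.seed(spec$seed)
  for (try in 1:10) {
    u <- stats::runif(spec$n)
    tt <- switch(spec$family,
      exponential = stats::qexp(u, rate = spec$params["rate"]),
      weibull = stats::qweibull(u, shape = spec$params["shape"],
                                scale = spec$params["scale"]),
      gamma = stats::qgamma(u, shape = spec$params["shape"],
                            rate = spec$params["rate"]),
      gompertz = flexsurv::qgompertz(u, shape = spec$params["shape"],
                                     rate = spec$params["rate"]),
      lognormal = stats::qlnorm(u, meanlog = spec$params["meanlog"],
                                sdlog = spec$params["sdlog"]),
      loglogistic = flexsurv::qllogis(u, shape = spec$params["shape"],
                                      scale = spec$params["scale"]))
    event <- as.integer(tt <= spec$censor_at)
    time <- pmin(tt, spec$censor_at)
    if (sum(event) > 0) break
    warning("all-censored simulation; regenerating (attempt ", try, ")")
  }
  if (sum(event) == 0) stop("simulation produced no events after 10 retries")
  ipd <- pseudo_ipd(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  sf <- stats::stepfun(fit$time, c(1, fit$surv))
  t_max <- max(time)
  risk_times <- spec$risk_times
  if (is.null(risk_times)) risk_times <- seq(0, t_max, length.out = 7)[-7]
  # digitizers align clicks with the risk-table gridlines; the click captures
  # the curve height just before the gridline (its left limit)
  at_risk_clicks <- pmax(risk_times[risk_times <= t_max] - 1e-6, 0)
  grid_t <- sort(unique(c(seq(0, t_max, length.out = spec$grid),
                          at_risk_clicks)))
  n_risk <- vapply(risk_times, function(x) sum(time >= x - 1e-9), numeric(1))
  km <- digitized_km(grid_t, cummin(sf(grid_t)), risk_times, n_risk,
                     label = sprintf("%s simulation", spec$family))
  list(km = km, true = true, ipd = ipd, n_events = sum(event))
}
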