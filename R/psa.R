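#' Parameter specification for sensitivity analyses
#'
#' Describes one uncertain input: its deterministic mean, its sampling
#' distribution (beta for utilities and probabilities, gamma for costs,
#' lognormal for hazard ratios) and its bounds. When no interval is
#' published, the 80-120% default interval around the mean is used. Interval
#' widths are treated as +/- 1.96 standard deviations and the distribution is
#' moment-matched.
#'
#' @param name Parameter name (see [apply_parameter()] for the recognised
#'   names; a vector of names moves several inputs jointly in the tornado).
#' @param mean Deterministic mean(s).
#' @param dist `"beta"`, `"gamma"`, `"lognormal"` or `"fixed"`.
#' @param lower,upper Interval bounds; default `0.8 * mean` / `1.2 * mean`.
#' @param label Display label (defaults to `name`).
#' @return A `parameter_spec` object.
#' @export
parameter_spec <- function(name, mean, dist = c("beta", "gamma", "lognormal",
                                                "fixed"),
                           lower = 0.8 * mean, upper = 1.2 * mean,
                           label = paste(name, collapse = "+")) {
  dist <- match.arg(dist)
  stopifnot(length(mean) == length(name), length(lower) == length(name),
            length(upper) == length(name))
  if (any(lower > mean | mean > upper))
    stop("bounds must bracket the mean for parameter ", label)
  if (dist == "beta" && any(lower < 0 | upper > 1))
    stop("beta parameter ", label, " needs bounds within [0, 1]")
  if (dist %in% c("gamma", "lognormal") && any(lower < 0))
    stop(dist, " parameter ", label, " needs non-negative bounds")
  structure(list(name = name, mean = mean, dist = dist, lower = lower,
                 upper = upper, label = label),
            class = "parameter_spec")
}

.beta_params <- function(m, sd, name = "parameter") {
  v <- sd^2
  if (v >= m * (1 - m))
    stop("interval of '", name, "' is incompatible with a beta distribution")
  k <- m * (1 - m) / v - 1
  list(shape1 = m * k, shape2 = (1 - m) * k)
}

.draw_one <- function(spec, n, j = 1) {
  m <- spec$mean[j]
  sd <- (spec$upper[j] - spec$lower[j]) / 3.92
  if (spec$dist == "fixed" || sd == 0) return(rep(m, n))
  switch(spec$dist,
    beta = {
      b <- .beta_params(m, sd, spec$name[j])
      stats::rbeta(n, b$shape1, b$shape2)
    },
    gamma = stats::rgamma(n, shape = (m / sd)^2, rate = m / sd^2),
    lognormal = {
      sdlog <- (log(spec$upper[j]) - log(spec$lower[j])) / 3.92
      stats::rlnorm(n, meanlog = log(m), sdlog = sdlog)
    })
}

#' Sample a joint parameter draw
#'
#' Draws each parameter independently from its moment-matched distribution.
#' One seeded generator is used and parameters are sampled in declared
#' order; that order is part of the reproducibility contract.
#'
#' @param specs List of [parameter_spec()]s.
#' @param seed Optional integer seed.
#' @param n Number of joint draws.
#' @return A numeric matrix (`n` rows, one column per scalar parameter).
#' @export
sample_parameters <- function(specs, seed = NULL, n = 1) {
  if (!is.null(seed)) set.seed(seed)
  cols <- list()
  for (spec in specs)
    for (j in seq_along(spec$name))
      cols[[spec$name[j]]] <- .draw_one(spec, n, j)
  do.call(cbind, cols)
}

#' Apply a named parameter value to a configuration
#'
#' Recognised names: the six transition probabilities
#' (`p_<sd_pd|sd_d|pd_d>_<control|intervention>`), the four utilities
#' (`u_sd`, `u_sd_ae_control`, `u_sd_ae_intervention`, `u_pd`), the hazard
#' ratios (`hr_pfs`, `hr_os`, `hr_sd_vs_pd`), the unit costs
#' (`cost_olar_control`, `cost_olar_intervention`, `cost_ae_control`,
#' `cost_ae_intervention`, `cost_followup`, `cost_lo_admin`), the indirect
#' cost multiplier `cost_indirect_scale`, the multipliers `os_probability`
#' (scales all four death probabilities) and `pfs_probability` (scales both
#' progression probabilities), and the discount rates `discount_costs`,
#' `discount_effects`.
#'
#' @param config A `model_config`.
#' @param name Parameter name.
#' @param value New value.
#' @return The modified configuration.
#' @export
apply_parameter <- function(config, name, value) {
  tr <- function(arm, field) {
    config$fixture$transitions[[arm]][[field]] <<- value
  }
  switch(name,
    p_sd_pd_control = tr("control", "sd_pd"),
    p_sd_pd_intervention = tr("intervention", "sd_pd"),
    p_sd_d_control = tr("control", "sd_d"),
    p_sd_d_intervention = tr("intervention", "sd_d"),
    p_pd_d_control = tr("control", "pd_d"),
    p_pd_d_intervention = tr("intervention", "pd_d"),
    u_sd = config$utilities$u_sd <- value,
    u_sd_ae_control = config$utilities$u_sd_ae_control <- value,
    u_sd_ae_intervention = config$utilities$u_sd_ae_intervention <- value,
    u_pd = config$utilities$u_pd <- value,
    hr_pfs = config$fixture$hazard_ratios$hr_pfs <- value,
    hr_os = config$fixture$hazard_ratios$hr_os <- value,
    hr_sd_vs_pd = config$fixture$hazard_ratios$hr_sd_vs_pd <- value,
    cost_olar_control = config$costs$olar_cycle_control <- value,
    cost_olar_intervention = config$costs$olar_cycle_intervention <- value,
    cost_ae_control = config$costs$ae_cost$control <- value,
    cost_ae_intervention = config$costs$ae_cost$intervention <- value,
    cost_followup = config$costs$followup_visit_cost <- value,
    cost_lo_admin = config$costs$lo_admin_per_injection <- value,
    cost_indirect_scale = config$scenario$indirect_scale <- value,
    discount_costs = config$discount$annual_rate_costs <- value,
    discount_effects = config$discount$annual_rate_effects <- value,
    os_probability = {
      for (arm in c("control", "intervention")) {
        config$fixture$transitions[[arm]]$sd_d <-
          config$fixture$transitions[[arm]]$sd_d * value
        config$fixture$transitions[[arm]]$pd_d <-
          config$fixture$transitions[[arm]]$pd_d * value
      }
    },
    pfs_probability = {
      for (arm in c("control", "intervention"))
        config$fixture$transitions[[arm]]$sd_pd <-
          config$fixture$transitions[[arm]]$sd_pd * value
    },
    stop("unknown parameter name: ", name))
  config
}

#' Default sampled-parameter specifications of the case study
#'
#' The published intervals are used where they exist (beta for utilities and
#' the intervention transition probabilities); inputs without a published
#' interval get the 80-120% default interval (beta for probabilities, gamma
#' for unit costs).
#'
#' @param config A `model_config`.
#' @return Named list of [parameter_spec()]s, in sampling order.
#' @export
default_parameter_specs <- function(config) {
  fx <- config$fixture
  u <- config$utilities
  co <- config$costs
  ci <- fx$transition_ci$intervention
  uc <- fx$utility_ci
  sp <- function(...) parameter_spec(...)
  specs <- list(
    sp("p_sd_pd_control", fx$transitions$control$sd_pd, "beta"),
    sp("p_sd_pd_intervention", fx$transitions$intervention$sd_pd, "beta",
       ci$sd_pd[1], ci$sd_pd[2]),
    sp("p_sd_d_control", fx$transitions$control$sd_d, "beta"),
    sp("p_sd_d_intervention", fx$transitions$intervention$sd_d, "beta",
       ci$sd_d[1], ci$sd_d[2]),
    sp("p_pd_d_control", fx$transitions$control$pd_d, "beta"),
    sp("p_pd_d_intervention", fx$transitions$intervention$pd_d, "beta",
       ci$pd_d[1], ci$pd_d[2]),
    sp("u_sd", u$u_sd, "beta", uc$u_sd[1], uc$u_sd[2]),
    sp("u_sd_ae_control", u$u_sd_ae_control, "beta",
       uc$u_sd_ae_control[1], uc$u_sd_ae_control[2]),
    sp("u_sd_ae_intervention", u$u_sd_ae_intervention, "beta",
       uc$u_sd_ae_intervention[1], uc$u_sd_ae_intervention[2]),
    sp("u_pd", u$u_pd, "beta", uc$u_pd[1], uc$u_pd[2]),
    sp("cost_olar_control", co$olar_cycle_control, "gamma"),
    sp("cost_olar_intervention", co$olar_cycle_intervention, "gamma"),
    sp("cost_ae_control", co$ae_cost$control, "gamma"),
    sp("cost_ae_intervention", co$ae_cost$intervention, "gamma"),
    sp("cost_followup", co$followup_visit_cost, "gamma"),
    sp("cost_indirect_scale", 1, "gamma"))
  names(specs) <- vapply(specs, function(s) s$label, character(1))
  specs
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation: for each draw, every sampled parameter is applied
#' to the configuration, the transition schedules are rebuilt, both arms are
#' run, and the incremental discounted cost (under both price scenarios) and
#' incremental QALYs are recorded. Draws producing an invalid schedule (a row
#' probability sum above 1) are rejected and redrawn; the count is reported
#' in the `n_redrawn` attribute.
#'
#' @param config A `model_config`.
#' @param n Number of draws (the case study uses 10,000).
#' @param seed Integer RNG seed.
#' @param specs Parameter specifications, by default
#'   [default_parameter_specs()].
#' @return A `psa_result`: data.frame with columns `draw`, `d_cost_initial`,
#'   `d_cost_increased`, `d_qaly`, `d_ly`; attributes `n`, `seed`,
#'   `n_redrawn`.
#' @export
run_psa <- function(config, n = config$psa$n, seed = config$psa$seed,
                    specs = default_parameter_specs(config)) {
  set.seed(seed)
  draws <- sample_parameters(specs, seed = NULL, n = n)
  bad <- .invalid_draws(draws)
  n_redrawn <- 0L
  guard <- 0L
  while (any(bad) && guard < 100L) {
    n_redrawn <- n_redrawn + sum(bad)
    draws[bad, ] <- sample_parameters(specs, seed = NULL, n = sum(bad))
    bad <- .invalid_draws(draws)
    guard <- guard + 1L
  }
  if (any(bad)) stop("could not produce valid parameter draws")
  out <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    cfg <- config
    for (nm in colnames(draws)) cfg <- apply_parameter(cfg, nm, draws[i, nm])
    ctrl <- evaluate_strategy(cfg, "control")
    int <- evaluate_strategy(cfg, "intervention", "initial")
    tr_int <- attr(int, "trace")
    cost_incr <- accumulate_costs(tr_int, cfg$costs, cfg$discount,
                                  "intervention", "increased",
                                  cfg$scenario$indirect_scale)
    out[i, ] <- c(int$cost - ctrl$cost, cost_incr - ctrl$cost,
                  int$qalys - ctrl$qalys, int$life_years - ctrl$life_years)
  }
  res <- data.frame(draw = seq_len(n), d_cost_initial = out[, 1],
                    d_cost_increased = out[, 2], d_qaly = out[, 3],
                    d_ly = out[, 4])
  if (!all(is.finite(out))) stop("PSA produced non-finite results")
  structure(res, n = n, seed = seed, n_redrawn = n_redrawn,
            class = c("psa_result", "data.frame"))
}

.invalid_draws <- function(draws) {
  bad <- rep(FALSE, nrow(draws))
  for (arm in c("control", "intervention")) {
    pp <- draws[, paste0("p_sd_pd_", arm)]
    pd <- draws[, paste0("p_sd_d_", arm)]
    qd <- draws[, paste0("p_pd_d_", arm)]
    bad <- bad | pp + pd >= 1 | qd >= 1
  }
  bad
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the intervention
#' is cost-effective is the fraction of PSA draws with positive net monetary
#' benefit, `wtp * dQALY - dCost > 0`, per price scenario.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid Numeric vector of willingness-to-pay values (euros/QALY).
#' @return data.frame with columns `wtp`, `scenario`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 120000, by = 1000)) {
  if (!nrow(psa)) stop("PSA result is empty")
  if (!length(wtp_grid)) stop("willingness-to-pay grid must be non-empty")
  rows <- lapply(c("initial", "increased"), function(sc) {
    dc <- psa[[paste0("d_cost_", sc)]]
    p <- vapply(wtp_grid, function(w) mean(w * psa$d_qaly - dc > 0),
                numeric(1))
    data.frame(wtp = wtp_grid, scenario = sc, probability = p)
  })
  do.call(rbind, rows)
}

#' Write PSA draws (the cost-effectiveness plane) to CSV
#'
#' One row per draw and price scenario: columns `draw`, `scenario`,
#' `d_cost`, `d_qaly`.
#'
#' @param psa A `psa_result`.
#' @param file Output CSV path.
#' @return The exported data.frame, invisibly.
#' @export
write_ce_plane <- function(psa, file) {
  out <- rbind(
    data.frame(draw = psa$draw, scenario = "initial",
               d_cost = psa$d_cost_initial, d_qaly = psa$d_qaly),
    data.frame(draw = psa$draw, scenario = "increased",
               d_cost = psa$d_cost_increased, d_qaly = psa$d_qaly))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Write a CEAC table to CSV
#'
#' @param cc A data.frame from [ceac()].
#' @param file Output CSV path.
#' @return `cc`, invisibly.
#' @export
write_ceac <- function(cc, file) {
  utils::write.csv(cc, file, row.names = FALSE)
  invisible(cc)
}
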