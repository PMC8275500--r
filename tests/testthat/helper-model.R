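# shared helpers for the suite

# a small constant-probability schedule for engine tests
toy_schedule <- function(n = 10, p_sd_pd = 0.1, p_sd_d = 0.05, p_pd_d = 0.2,
                         strategy = "control") {
  transition_schedule(rep(p_sd_pd, n), rep(p_sd_d, n), rep(p_pd_d, n),
                      strategy = strategy)
}

# the three-point digitized curve of the no-censoring toy case
toy_km <- function() {
  digitized_km(c(0, 2, 5), c(1, 0.8, 0.4), risk_time = c(0, 6),
               n_risk = c(10, 4))
}

# Kaplan-Meier step function of a pseudo-IPD object
km_stepfun <- function(ipd) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  stats::stepfun(sf$time, c(1, sf$surv))
}

base_config <- function(price = "increased", ...) {
  make_case_config(price, ...)
}

# degenerate parameter specs: every sampled parameter fixed at its mean
degenerate_specs <- function(config) {
  lapply(default_parameter_specs(config), function(s) {
    parameter_spec(s$name, s$mean, "fixed", s$mean, s$mean, label = s$label)
  })
}
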