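test_that("exponential fit equals the closed-form events/exposure MLE", {
  set.seed(4)
  tt <- rexp(400, 0.07)
  ev <- as.integer(tt <= 20)
  ipd <- pseudo_ipd(pmin(tt, 20), ev)
  fit <- fit_parametric(ipd, "exponential")
  expect_equal(fit$params[["rate"]], sum(ev) / sum(pmin(tt, 20)),
               tolerance = 1e-4)
  expect_equal(fit$aic, 2 - 2 * fit$log_likelihood)
})

test_that("each family recovers its generating parameters at n = 1000", {
  cases <- list(
    list(family = "exponential", params = c(rate = 0.06)),
    list(family = "weibull", params = c(shape = 1.4, scale = 18)),
    list(family = "gamma", params = c(shape = 1.8, rate = 0.09)))
  for (cs in cases) {
    sim <- simulate_km(sim_spec(cs$family, cs$params, n = 1000,
                                censor_at = 45, seed = 2))
    fit <- fit_parametric(sim$ipd, cs$family)
    expect_lt(max(abs(fit$params / cs$params - 1)), 0.15,
              label = paste(cs$family, "relative parameter error"))
  }
})

test_that("fitting is refused without events", {
  ipd <- pseudo_ipd(c(5, 8, 12), c(0, 0, 0))
  expect_error(fit_parametric(ipd, "exponential"), "at least 2 events")
})

test_that("AIC selection prefers the generating family in most replicates", {
  wins <- 0L
  for (sd in 1:7) {
    sim <- simulate_km(sim_spec("exponential", c(rate = 0.08), n = 500,
                                censor_at = 40, seed = sd))
    best <- select_best(sim$ipd, c("exponential", "gamma"))
    wins <- wins + (best$family == "exponential")
  }
  expect_gt(wins, 3L)
})

test_that("select_best handles a single candidate and total failure", {
  sim <- simulate_km(sim_spec("exponential", c(rate = 0.08), n = 100,
                              censor_at = 40, seed = 1))
  expect_equal(select_best(sim$ipd, "weibull")$family, "weibull")
  all_cens <- pseudo_ipd(c(1, 2, 3), c(0, 0, 0))
  expect_error(select_best(all_cens, c("exponential", "gamma")),
               "all candidate families failed")
})

test_that("survival functions start at 1 and are non-increasing", {
  models <- list(
    parametric_survival("exponential", c(rate = 0.1)),
    parametric_survival("weibull", c(shape = 0.8, scale = 12)),
    parametric_survival("gamma", c(shape = 2, rate = 0.15)),
    parametric_survival("gompertz", c(shape = 0.05, rate = 0.01)),
    parametric_survival("lognormal", c(meanlog = 2, sdlog = 0.7)),
    parametric_survival("loglogistic", c(shape = 1.5, scale = 10)))
  grid <- seq(0, 120, by = 0.25)
  for (m in models) {
    s <- surv_prob(m, grid)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12), label = paste(m$family, "monotone"))
    expect_true(all(s > 0 & s <= 1))
  }
})

test_that("per-cycle probabilities follow the closed form and hazard shape", {
  exp_yr <- parametric_survival("exponential", c(rate = 0.1),
                                time_unit = "years")
  expect_equal(cycle_probability(exp_yr, 0), 1 - exp(-0.1 * 28 / 365.25),
               tolerance = 1e-9)
  # memoryless: identical for every cycle
  p <- cycle_probability(exp_yr, 0:50)
  expect_equal(max(p) - min(p), 0)
  # increasing hazard (gamma shape > 1): strictly increasing in cycle index
  gam <- parametric_survival("gamma", c(shape = 2.5, rate = 0.05))
  pg <- cycle_probability(gam, 0:100)
  expect_true(all(diff(pg) > 0))
})

test_that("hazard-ratio application is exact, monotone and guarded", {
  expect_equal(apply_hazard_ratio(0.0854, 1), 0.0854)
  expect_equal(apply_hazard_ratio(0.0854, 0.21), 1 - 0.9146^0.21,
               tolerance = 1e-12)
  expect_equal(apply_hazard_ratio(0.5, 2), 0.75)
  # monotone in both arguments
  p <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(apply_hazard_ratio(p, 0.6)) > 0))
  hr <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(apply_hazard_ratio(0.3, hr)) > 0))
  expect_error(apply_hazard_ratio(1, 0.5), "undefined")
  expect_error(apply_hazard_ratio(0.5, -1), "positive")
})

test_that("fit summaries can be exported", {
  sim <- simulate_km(sim_spec("exponential", c(rate = 0.08), n = 200,
                              censor_at = 40, seed = 1))
  fits <- list(fit_parametric(sim$ipd, "exponential"),
               fit_parametric(sim$ipd, "gamma"))
  f <- tempfile(fileext = ".csv")
  out <- write_fit_summary(fits, f)
  expect_true(file.exists(f))
  expect_equal(out$family, c("exponential", "gamma"))
  expect_true(all(is.finite(out$aic)))
})
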