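test_that("per-cycle discount factors match the published per-cycle rates", {
  spec <- discount_spec()
  # 4%/year is ~0.3% per 28-day cycle, 1.5%/year ~0.11%
  expect_equal(1 / discount_factor(spec, "costs", 1) - 1, 0.003,
               tolerance = 0.01)
  expect_equal(1 / discount_factor(spec, "effects", 1) - 1, 0.0011,
               tolerance = 0.04)
  expect_equal(discount_factor(spec, "costs", 0), 1)
  z <- discount_spec(0, 0)
  expect_equal(discount_factor(z, "costs", 0:50), rep(1, 51))
  expect_error(discount_factor(spec, "costs", -1), "non-negative")
})

test_that("QALY accumulation follows the closed form", {
  # one cycle fully in SD, no discounting, no AEs
  sched <- transition_schedule(0, 0, 0, "control")
  tr <- run_cohort(sched)
  tr <- tr[1, , drop = FALSE]
  attr(tr, "cycle_days") <- 28
  u <- utility_set(ae_fraction = c(control = 0, intervention = 0))
  eff <- accumulate_qalys(tr, u, discount_spec(0, 0), "control")
  expect_equal(eff$qalys, 0.771 * 28 / 365.25, tolerance = 1e-12)
  # all utilities 1: QALYs equal life-years
  u1 <- utility_set(u_sd = 1, u_sd_ae_control = 1, u_sd_ae_intervention = 1,
                    u_pd = 1)
  cfg <- base_config()
  trace <- attr(evaluate_strategy(cfg, "control"), "trace")
  eff1 <- accumulate_qalys(trace, u1, cfg$discount, "control")
  expect_equal(eff1$qalys, eff1$life_years)
})

test_that("QALYs never exceed life-years", {
  cfg <- base_config()
  for (arm in c("control", "intervention")) {
    out <- evaluate_strategy(cfg, arm)
    expect_lte(out$qalys, out$life_years)
  }
})

test_that("zero unit costs give zero totals", {
  cfg <- base_config()
  trace <- attr(evaluate_strategy(cfg, "intervention"), "trace")
  zero <- cost_schedule(lo_price_initial = 0, lo_price_increased = 0,
                        lo_admin_per_injection = 0, olar_cycle_control = 0,
                        olar_cycle_intervention = 0,
                        ae_cost = c(control = 0, intervention = 0),
                        followup_visit_cost = 0,
                        indirect_by_age = make_indirect_cost_table(0, 0, 0))
  expect_equal(accumulate_costs(trace, zero, cfg$discount, "intervention",
                                "increased"), 0)
})

test_that("the price scenarios differ by the discounted injection increment", {
  cfg <- base_config()
  trace <- attr(evaluate_strategy(cfg, "intervention"), "trace")
  c_lo <- accumulate_costs(trace, cfg$costs, cfg$discount, "intervention",
                           "initial")
  c_hi <- accumulate_costs(trace, cfg$costs, cfg$discount, "intervention",
                           "increased")
  inj <- trace$cycle %in% cfg$costs$lo_injection_cycles
  df <- discount_factor(cfg$discount, "costs", trace$cycle)
  expected <- sum((90000 - 16000) / 4 * trace$occ_sd[inj] * df[inj])
  expect_equal(c_hi - c_lo, expected, tolerance = 1e-12)
  expect_gt(c_hi, c_lo)
})

test_that("the price scenario is mandatory for the intervention arm", {
  cfg <- base_config()
  trace <- attr(evaluate_strategy(cfg, "intervention"), "trace")
  expect_error(accumulate_costs(trace, cfg$costs, cfg$discount,
                                "intervention"), "price_scenario")
})

test_that("zero discount rates reproduce the plain sums", {
  cfg <- base_config()
  cfg$discount <- discount_spec(0, 0)
  out <- evaluate_strategy(cfg, "control")
  trace <- attr(out, "trace")
  # independent oracle: direct summation without discounting
  cyc_years <- 28 / 365.25
  u <- cfg$utilities
  u_eff <- rep(u$u_sd, nrow(trace))
  u_eff[trace$cycle < u$ae_window_cycles] <-
    (1 - u$ae_fraction$control) * u$u_sd +
    u$ae_fraction$control * u$u_sd_ae_control
  expect_equal(out$qalys,
               sum((trace$occ_sd * u_eff + trace$occ_pd * u$u_pd) * cyc_years))
  expect_equal(out$life_years,
               sum((trace$occ_sd + trace$occ_pd) * cyc_years))
})

test_that("ICERs follow the published arithmetic and rounding rules", {
  a <- outcome_totals("intervention", 70491 + 97725, 1.79 + 1.82, 2.68 + 2.41,
                      "increased")
  b <- outcome_totals("control", 70491, 1.79, 2.68)
  iq <- icer(a, b, "qaly")
  expect_equal(iq$value, 97725 / 1.82)
  expect_equal(iq$rounded, 53700)
  expect_equal(iq$dominance, "none")
  a_init <- outcome_totals("intervention", 70491 + 34767, 1.79 + 1.82,
                           2.68 + 2.41, "initial")
  il <- icer(a_init, b, "ly")
  expect_equal(il$rounded, 14400)
  # zero incremental cost
  a0 <- outcome_totals("intervention", 70491, 3.61, 5.09, "initial")
  expect_equal(icer(a0, b, "qaly")$value, 0)
  expect_equal(icer(a0, b, "qaly")$dominance, "dominant")
  # zero incremental effect: flagged, not a number
  same <- outcome_totals("intervention", 80000, 1.79, 2.68, "initial")
  iz <- icer(same, b, "qaly")
  expect_true(is.na(iz$value))
  expect_equal(iz$dominance, "dominated")
})

test_that("a common cost stream leaves the ICER unchanged", {
  cfg <- base_config()
  res <- run_deterministic(cfg)
  shift <- 12345.6
  a <- res$intervention; b <- res$control
  a$cost <- a$cost + shift
  b$cost <- b$cost + shift
  expect_equal(icer(a, b, "qaly")$value, res$icer_qaly$value)
})

test_that("net monetary benefit matches the ICER threshold identity", {
  a <- outcome_totals("intervention", 70491 + 97725, 1.79 + 1.82, 5.09,
                      "increased")
  b <- outcome_totals("control", 70491, 1.79, 2.68)
  expect_equal(net_monetary_benefit(a, b, 80000), 80000 * 1.82 - 97725)
  expect_equal(net_monetary_benefit(a, b, 0), -97725)
  for (wtp in c(20000, 53000, 54000, 100000)) {
    nmb <- net_monetary_benefit(a, b, wtp)
    expect_equal(nmb > 0, icer(a, b, "qaly")$value < wtp)
  }
})

test_that("proportional shortfall maps to the Dutch threshold classes", {
  ps <- proportional_shortfall(1.79, 18.9)
  expect_equal(ps$shortfall, (18.9 - 1.79) / 18.9)
  expect_equal(ps$wtp, 80000)
  expect_equal(proportional_shortfall(18.9, 18.9)$shortfall, 0)
  expect_equal(proportional_shortfall(18.9, 18.9)$wtp, 20000)
  expect_equal(proportional_shortfall(0, 18.9)$shortfall, 1)
  expect_equal(proportional_shortfall(10, 18.9)$wtp, 50000)
  expect_error(proportional_shortfall(-1, 18.9))
  expect_error(proportional_shortfall(1, 0))
})
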