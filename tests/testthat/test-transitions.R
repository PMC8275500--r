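test_that("death split solves the occupancy-weighted equation", {
  # bisection oracle, independently coded
  oracle <- function(p_os, w_sd, rho) {
    f <- function(h) w_sd * (1 - exp(-rho * h)) + (1 - w_sd) * (1 - exp(-h)) -
      p_os
    h <- uniroot(f, c(0, 50), tol = 1e-14)$root
    c(1 - exp(-rho * h), 1 - exp(-h))
  }
  sp <- split_death_probability(0.10, 0.5, 0.44)
  ref <- oracle(0.10, 0.5, 0.44)
  expect_equal(sp$p_sd, ref[1], tolerance = 1e-9)
  expect_equal(sp$p_pd, ref[2], tolerance = 1e-9)
  # recombination reproduces the overall probability
  expect_equal(0.5 * sp$p_sd + 0.5 * sp$p_pd, 0.10, tolerance = 1e-10)
  # hazards in the requested ratio
  expect_equal(log(1 - sp$p_sd) / log(1 - sp$p_pd), 0.44, tolerance = 1e-9)
  # unit ratio: symmetric split
  sp1 <- split_death_probability(0.10, 0.3, 1)
  expect_equal(sp1$p_sd, 0.10, tolerance = 1e-10)
  expect_equal(sp1$p_pd, 0.10, tolerance = 1e-10)
})

test_that("curve-derived schedules recombine to the OS curve per cycle", {
  pfs <- parametric_survival("exponential", c(rate = 0.089))
  os <- parametric_survival("gamma", c(shape = 1.5, rate = 0.035))
  hrs <- hazard_ratio_set(0.21, 0.54, 0.44)
  lt <- make_life_table()
  for (strat in c("control", "intervention")) {
    sched <- derive_transitions(pfs, os, hrs, lt, strat, n_cycles = 200)
    p_os <- cycle_probability(os, 0:199)
    if (strat == "intervention")
      p_os <- apply_hazard_ratio(p_os, hrs$hr_os)
    # replay the occupancy to recover the weights used by the split
    occ <- c(1, 0)
    n_check <- if (is.null(sched$override_cycle)) 200 else sched$override_cycle
    for (i in seq_len(n_check)) {
      alive <- sum(occ)
      w <- occ[1] / alive
      recomb <- w * sched$p_sd_d[i] + (1 - w) * sched$p_pd_d[i]
      expect_lt(abs(recomb - p_os[i]), 1e-10)
      occ <- c(occ[1] * (1 - sched$p_sd_pd[i] - sched$p_sd_d[i]),
               occ[2] * (1 - sched$p_pd_d[i]) + occ[1] * sched$p_sd_pd[i])
    }
  }
})

test_that("the life-table override engages once and never disengages", {
  fx <- case_study_fixture()
  sched <- schedule_from_table(fx, "intervention", 783)
  expect_false(is.null(sched$override_cycle))
  k <- sched$override_cycle + 1
  p_bg <- background_mortality(fx$life_table, fx$start_age, 783,
                               male_fraction = fx$male_fraction$intervention)
  expect_equal(sched$p_sd_d[k:783], pmin(p_bg, 1)[k:783])
  # before the crossing the disease-specific probability rules
  expect_true(all(sched$p_sd_d[1:(k - 1)] >= p_bg[1:(k - 1)]))
})

test_that("a closing life-table row forces full absorption", {
  lt <- make_life_table(max_age = 90)
  fx <- case_study_fixture(life_table = lt)
  sched <- schedule_from_table(fx, "intervention", 600)
  trace <- run_cohort(sched, absorb_threshold = 0.999999)
  expect_lte(max(trace$age), 91)
  expect_gt(trace$occ_dead[nrow(trace)], 0.999999)
})

test_that("tabulated schedules anchor cycle 0 at the printed probabilities", {
  fx <- case_study_fixture()
  ctrl <- schedule_from_table(fx, "control", 100)
  # the SD-exit (PFS event) probability at cycle 0 equals the printed 0.0854,
  # split between progression and death in SD
  expect_equal(ctrl$p_sd_pd[1] + ctrl$p_sd_d[1], 0.0854)
  expect_equal(ctrl$p_sd_d[1], 0.0095)
  expect_equal(ctrl$p_pd_d[1], 0.0216)
  int <- schedule_from_table(fx, "intervention", 100)
  m <- as.matrix(int, cycle = 0)
  expect_equal(unname(m["PD", ]), c(0, 1 - 0.0116, 0.0116))
  # every row of every cycle is stochastic
  for (cyc in c(0, 10, 50, 99)) {
    m <- as.matrix(ctrl, cycle = cyc)
    expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)
    expect_equal(unname(m["Dead", ]), c(0, 0, 1))
  }
})

test_that("missing fixture probabilities are rejected", {
  fx <- case_study_fixture()
  fx$transitions$intervention$sd_d <- NA
  expect_error(schedule_from_table(fx, "intervention", 10), "missing")
})

test_that("schedules export for audit", {
  sched <- toy_schedule(5)
  f <- tempfile(fileext = ".csv")
  out <- write_schedule(sched, f)
  expect_equal(nrow(out), 5)
  expect_equal(names(out), c("cycle", "p_sd_pd", "p_sd_d", "p_pd_d"))
})
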