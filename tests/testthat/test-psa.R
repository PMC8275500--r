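test_that("beta moment matching reproduces the published interval", {
  # u_pd: mean 0.612, 95% interval 0.564-0.659
  b <- ceanet:::.beta_params(0.612, (0.659 - 0.564) / 3.92)
  expect_equal(b$shape1, 246.9, tolerance = 0.005)
  expect_equal(b$shape2, 156.5, tolerance = 0.005)
  spec <- parameter_spec("u_pd", 0.612, "beta", 0.564, 0.659)
  set.seed(1)
  draws <- ceanet:::.draw_one(spec, 10000)
  expect_lt(abs(mean(draws) - 0.612), 0.005)
})

test_that("degenerate specs draw constants and seeds reproduce draws", {
  spec <- parameter_spec("x", 0.5, "beta", 0.5, 0.5)
  expect_equal(ceanet:::.draw_one(spec, 5), rep(0.5, 5))
  specs <- default_parameter_specs(base_config())
  d1 <- sample_parameters(specs, seed = 11, n = 3)
  d2 <- sample_parameters(specs, seed = 11, n = 3)
  expect_identical(d1, d2)
  expect_equal(ncol(d1), 16L)
})

test_that("incompatible intervals are rejected naming the parameter", {
  expect_error(parameter_spec("u_sd", 1.2, "beta", 1.1, 1.3), "u_sd")
  wide <- parameter_spec("p", 0.5, "beta", 0, 1)
  wide$upper <- 3  # sd too large for the support
  expect_error(ceanet:::.draw_one(wide, 1), "incompatible")
})

test_that("a degenerate PSA reproduces the deterministic result exactly", {
  cfg <- base_config()
  det <- run_deterministic(cfg, "initial")
  psa <- run_psa(cfg, n = 3, seed = 5, specs = degenerate_specs(cfg))
  expect_equal(psa$d_qaly, rep(det$icer_qaly$delta_effect, 3))
  expect_equal(psa$d_cost_initial,
               rep(det$intervention$cost - det$control$cost, 3))
})

test_that("identical seeds give bit-identical PSA results", {
  cfg <- base_config()
  p1 <- run_psa(cfg, n = 25, seed = 42)
  p2 <- run_psa(cfg, n = 25, seed = 42)
  expect_identical(p1$d_cost_increased, p2$d_cost_increased)
  expect_identical(p1$d_qaly, p2$d_qaly)
  p3 <- run_psa(cfg, n = 25, seed = 43)
  expect_false(identical(p3$d_qaly, p1$d_qaly))
})

test_that("CEAC probabilities behave as net-benefit fractions", {
  # brute-force oracle on four hand-set draws
  psa <- structure(data.frame(draw = 1:4,
                              d_cost_initial = c(-100, 40000, 90000, 120000),
                              d_cost_increased = c(-100, 40000, 90000, 120000),
                              d_qaly = c(1, 1, 1.5, 2),
                              d_ly = c(1, 1, 1.5, 2)),
                   class = c("psa_result", "data.frame"))
  cc <- ceac(psa, 50000)
  # NMB at 50k: 50100, 10000, -15000, -20000 -> 2 of 4 positive
  expect_equal(cc$probability, c(0.5, 0.5))
  # all dominant draws: probability 1 at every threshold
  psa1 <- psa; psa1$d_cost_initial <- rep(-100, 4)
  psa1$d_cost_increased <- rep(-100, 4)
  expect_true(all(ceac(psa1, c(0, 1e4, 1e5))$probability == 1))
  expect_error(ceac(psa, numeric(0)), "non-empty")
})

test_that("CEAC is monotone and the initial price dominates the increased", {
  cfg <- base_config()
  psa <- run_psa(cfg, n = 150, seed = 7)
  grid <- seq(0, 120000, by = 10000)
  cc <- ceac(psa, grid)
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  for (sc in c("initial", "increased")) {
    p <- cc$probability[cc$scenario == sc]
    if (all(psa$d_qaly > 0)) expect_true(all(diff(p) >= 0))
  }
  p_init <- cc$probability[cc$scenario == "initial"]
  p_incr <- cc$probability[cc$scenario == "increased"]
  expect_true(all(p_init >= p_incr))
})

test_that("CE-plane and CEAC tables export to CSV", {
  cfg <- base_config()
  psa <- run_psa(cfg, n = 10, seed = 1)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  out <- write_ce_plane(psa, f1)
  expect_equal(nrow(out), 20)
  cc <- ceac(psa, c(50000, 80000))
  write_ceac(cc, f2)
  expect_equal(nrow(utils::read.csv(f2)), 4)
})
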