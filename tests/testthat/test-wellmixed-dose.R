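test_that("calibration inverts the steady model (cross-checked by root finding)", {
  G <- calibrate_generation(221.60, 0.3, 10, 7.56e-3)
  # independent oracle: invert wellmixed_steady numerically
  oracle <- stats::uniroot(function(g) {
    wellmixed_steady(wellmixed_params(G = g, ach = 0.3, c_out = 10,
                                      lambda_rn = 7.56e-3)) - 221.60
  }, c(0, 1000), tol = 1e-12)$root
  expect_equal(G, oracle, tolerance = 1e-9)
  expect_equal(G, 65.1, tolerance = 1e-3 * 65)
  # no indoor source at the outdoor-supported floor
  lam <- 0.3 + 7.56e-3
  expect_equal(calibrate_generation(0.3 * 10 / lam, 0.3, 10, 7.56e-3), 0,
               tolerance = 1e-9)
  expect_error(calibrate_generation(1, 0.3, 10, 7.56e-3), "floor")
})

test_that("calibrated steady model reproduces the published analytical column", {
  G <- calibrate_generation(221.60, 0.3, 10, 7.56e-3)
  ach <- c(0.5, 1, 1.5, 2, 4.3)
  expected <- c(138.22, 74.59, 53.17, 42.42, 25.11)
  got <- vapply(ach, function(a) {
    wellmixed_steady(wellmixed_params(G = G, ach = a, c_out = 10,
                                      lambda_rn = 7.56e-3))
  }, numeric(1))
  expect_true(all(abs(got - expected) <= 0.01))
  # round-trip identity over a range of feasible observations
  for (x in c(15, 74.59, 300)) {
    g <- calibrate_generation(x, 1, 10, 7.56e-3)
    expect_equal(wellmixed_steady(wellmixed_params(G = g, ach = 1)), x,
                 tolerance = 1e-10)
  }
})

test_that("steady state handles degenerate sources and the outdoor flag", {
  expect_equal(wellmixed_steady(wellmixed_params(G = 0, ach = 1, c_out = 0)), 0)
  # without outdoor inflow the literal form G / lambda is returned
  p <- wellmixed_params(G = 65, ach = 1, c_out = 10,
                        include_outdoor_inflow = FALSE)
  expect_equal(wellmixed_steady(p), 65 / (1 + p$lambda_rn))
  expect_error(wellmixed_params(G = 10, ach = 0, lambda_rn = 0), "positive")
})

test_that("time series starts at C0 and approaches the steady value", {
  p <- wellmixed_params(G = 65.155, ach = 1, c0 = 3)
  css <- wellmixed_steady(p)
  lam <- p$lambda_rn + p$ach
  expect_equal(wellmixed_timeseries(p, 0), 3)
  expect_equal(wellmixed_timeseries(p, 5 / lam), css, tolerance = 0.01)
  expect_equal(wellmixed_timeseries(p, 20 / lam), css, tolerance = 1e-8)
  ts <- wellmixed_timeseries(p, seq(0, 10, by = 0.5))
  expect_true(all(diff(ts) > 0))  # monotone approach from below
  pfix <- wellmixed_params(G = 65.155, ach = 1, c0 = css)
  expect_equal(wellmixed_timeseries(pfix, c(0, 1, 7)), rep(css, 3))
  expect_error(wellmixed_timeseries(p, -1), "non-negative")
})

test_that("steady value decreases with ventilation when the source dominates", {
  G <- 65.155
  ach <- c(0.3, 0.5, 1, 1.5, 2, 4.3)
  vals <- vapply(ach, function(a) {
    wellmixed_steady(wellmixed_params(G = G, ach = a))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("annual effective dose follows C * F * t * K in mSv", {
  d <- dose_params()
  expect_equal(annual_effective_dose(70.21, d), 0.674, tolerance = 1e-3)
  expect_equal(annual_effective_dose(66.25, d), 0.636, tolerance = 1e-3)
  expect_equal(annual_effective_dose(170.7, d), 1.639, tolerance = 1e-3)
  expect_equal(annual_effective_dose(154, d), 1.478, tolerance = 1e-3)
  expect_equal(annual_effective_dose(0, d), 0)
  # linear in each factor
  expect_equal(annual_effective_dose(140, d), 2 * annual_effective_dose(70, d))
  d2 <- dose_params(F = 0.8)
  expect_equal(annual_effective_dose(70, d2), 2 * annual_effective_dose(70, d))
  expect_error(dose_params(occupancy = 9000), "occupancy")
})
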