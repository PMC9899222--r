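test_that("percentage difference matches the published pairs", {
  expect_equal(percentage_difference(74.59, 70.21), 5.87, tolerance = 1e-2)
  expect_equal(percentage_difference(25.11, 20.17), 19.67, tolerance = 1e-2)
  expect_equal(percentage_difference(42, 42), 0)
  expect_error(percentage_difference(0, 10), "positive")
  # scale invariance
  expect_equal(percentage_difference(3 * 74.59, 3 * 70.21),
               percentage_difference(74.59, 70.21))
})

test_that("relative deviation is absolute and scale invariant", {
  expect_equal(relative_deviation(77, 82), 6.1, tolerance = 1e-1)
  expect_equal(relative_deviation(81, 82), 1.2, tolerance = 5e-2)
  expect_equal(relative_deviation(90, 82), relative_deviation(74, 82))
  expect_equal(relative_deviation(55, 55), 0)
  expect_true(all(relative_deviation(c(10, 200), 82) >= 0))
  expect_equal(relative_deviation(2 * 77, 2 * 82), relative_deviation(77, 82))
  expect_error(relative_deviation(77, 0), "positive")
})

test_that("analytical comparison table reproduces the published layout", {
  tab <- utils::read.csv(system.file("extdata", "ach_table.csv",
                                     package = "radonroom"))
  G <- calibrated_G()
  params <- wellmixed_params(G = G, ach = 1)
  rep2 <- build_table2(tab$ach,
                       list(open = tab$numerical_open,
                            closed = tab$numerical_closed), params)
  expect_true(all(abs(rep2$table$analytical - tab$analytical) <= 0.01))
  expect_equal(rep2$table$difference_pct_closed, tab$difference_pct_closed,
               tolerance = 5e-3)
  expect_equal(rep2$table$difference_pct_open, tab$difference_pct_open,
               tolerance = 5e-3)
  # degenerate cases
  one <- build_table2(1, 74.59, params)
  expect_equal(nrow(one$table), 1)
  same <- build_table2(tab$ach, list(x = rep2$table$analytical), params)
  expect_true(all(abs(same$table$difference_pct_x) < 1e-12))
  expect_error(build_table2(c(1, 2), 70, params), "lengths differ")
})

test_that("detector comparison is self-consistent at zero noise", {
  run <- small_room_run()
  rn <- solve_radon(run$grid, run$flow, source_spec(), "boundary_flux")
  pts <- detector_points()
  ms <- synthetic_measurements(rn, run$grid, pts,
                               noise_model(sigma = 0, seed = 11))
  rep_ <- build_detector_comparison(rn, run$grid, ms)
  expect_true(all(abs(rep_$table$relative_deviation_pct) < 1e-10))
  # permutation invariance of record order
  perm <- ms
  perm$records <- perm$records[rev(seq_len(nrow(perm$records))), ]
  rep_p <- build_detector_comparison(rn, run$grid, perm)
  expect_equal(sort(rep_p$table$predicted), sort(rep_$table$predicted))
  expect_error(build_detector_comparison(rn, run$grid,
                                         measurement_set("x", data.frame(
                                           x = numeric(0), y = numeric(0),
                                           z = numeric(0),
                                           concentration = numeric(0)))),
               "empty")
})

test_that("published open-door breathing-zone rows give the reported deviations", {
  sets <- read_measurements(system.file("extdata", "measurements_open.csv",
                                        package = "radonroom"))
  sim <- sets$Simulation$records
  z100 <- sim[abs(sim$z - 1.0) < 1e-9, ]
  expect_equal(mean(z100$concentration), 82.2)  # printed as 82
  ag <- sets$AlphaGUARD$records
  ag100 <- ag[abs(ag$z - 1.0) < 1e-9, ]
  rep_ <- build_detector_comparison(
    measurements = measurement_set("AlphaGUARD", ag100),
    predictions = z100$concentration[match(ag100$point, z100$point)])
  dev_means <- rep_$summary$deviation_of_means_pct
  expect_equal(dev_means, abs(mean(ag100$concentration) - 82.2) / 82.2 * 100)
  expect_equal(dev_means, 6.1, tolerance = 2e-2)  # reported as about 7%
  rad7 <- sets$RAD7$records
  rad7 <- rad7[abs(rad7$z - 1.0) < 1e-9, ]
  rep7 <- build_detector_comparison(
    measurements = measurement_set("RAD7", rad7),
    predictions = z100$concentration[match(rad7$point, z100$point)])
  expect_equal(rep7$summary$deviation_of_means_pct,
               abs(mean(rad7$concentration) - mean(z100$concentration)) /
                 mean(z100$concentration) * 100)
  expect_equal(rep7$summary$deviation_of_means_pct, 1.46,
               tolerance = 2e-2)  # reported as about 2%
})

test_that("multiplicative noise yields the half-normal mean deviation", {
  n <- 1e4
  pts <- data.frame(x = rep(1.5, n), y = rep(2, n), z = rep(1.4, n))
  ms <- synthetic_measurements(function(x, y, z) rep(100, length(x)), NULL,
                               pts, noise_model("multiplicative_lognormal",
                                                0.1, seed = 99))
  md <- mean(relative_deviation(ms$records$concentration, 100))
  expect_equal(md, 0.1 * sqrt(2 / pi) * 100, tolerance = 0.03)
})
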