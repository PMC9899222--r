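test_that("volumetric generation rate is sum(E A) / V", {
  g <- volumetric_generation_rate(3.1, c(11.2, 11.2, 8.4, 8.4, 12, 12), 33.6)
  expect_equal(g$per_hour, 3.1 * 63.2 / 33.6, tolerance = 1e-12)
  expect_equal(g$per_hour, 5.83, tolerance = 1e-2)
  expect_equal(g$per_second, g$per_hour / 3600)
  expect_equal(volumetric_generation_rate(3.1, 12, 33.6)$per_hour, 1.107,
               tolerance = 1e-3)
  expect_equal(volumetric_generation_rate(0, c(10, 20), 33.6)$per_hour, 0)
  expect_error(volumetric_generation_rate(3.1, 12, 0), "V must be positive")
})

test_that("source-free room relaxes to the outdoor concentration", {
  run <- small_room_run()
  # without decay the steady state is exactly uniform at c_out
  src0 <- source_spec(exhalation = 0, c_out = 10, decay_constant = 0)
  f0 <- solve_radon(run$grid, run$flow, src0, "boundary_flux")
  expect_equal(range(f0$concentration), c(10, 10), tolerance = 1e-5)
  # with decay the field sits slightly below c_out (about lambda_rn / ach)
  src1 <- source_spec(exhalation = 0, c_out = 10)
  f1 <- solve_radon(run$grid, run$flow, src1, "boundary_flux")
  expect_true(all(f1$concentration <= 10 + 1e-9))
  expect_true(all(f1$concentration >= 10 * 0.97))
  expect_equal(f1$volume_average, 10, tolerance = 0.012)
})

test_that("strong-mixing limit agrees with the well-mixed model", {
  run <- small_room_run()
  G <- calibrated_G()
  src <- source_spec(diffusion = 1.2e-5 * 1e6)
  rn <- solve_radon(run$grid, run$flow, src, "volumetric", G = G)
  wm <- wellmixed_steady(wellmixed_params(G = G, ach = 1))
  expect_equal(rn$volume_average, wm, tolerance = 0.02)
})

test_that("volume average is the volume-weighted mean", {
  grid <- generate_grid(room_geometry(), 5)  # even cell count along z
  uni <- array(42, c(grid$nx, grid$ny, grid$nz))
  expect_equal(volume_average(uni, grid), 42)
  half <- uni
  half[, , seq_len(grid$nz / 2)] <- 0
  half[, , grid$nz / 2 + seq_len(grid$nz / 2)] <- 84
  expect_equal(volume_average(half, grid), 42)
  linz <- array(rep(grid$zc, each = grid$nx * grid$ny), c(grid$nx, grid$ny, grid$nz))
  expect_equal(volume_average(linz, grid), grid$Lz / 2, tolerance = 1e-12)
})

test_that("trilinear sampling reproduces uniform and linear fields", {
  geom <- room_geometry()
  grid <- generate_grid(geom, 5)
  uni <- array(7, c(grid$nx, grid$ny, grid$nz))
  pts <- data.frame(x = c(0.05, 1.2, 2.95), y = c(0.1, 2.2, 3.9),
                    z = c(0.7, 1.33, 2.75))
  expect_equal(sample_at(uni, grid, pts), rep(7, 3))
  # linear field: exact at cell centres and at interior points
  lin <- array(0, c(grid$nx, grid$ny, grid$nz))
  for (k in seq_len(grid$nz)) for (j in seq_len(grid$ny))
    lin[, j, k] <- 2 * grid$xc + 3 * grid$yc[j] - grid$zc[k]
  centres <- data.frame(x = grid$xc[3], y = grid$yc[5], z = grid$zc[2])
  expect_equal(sample_at(lin, grid, centres),
               2 * grid$xc[3] + 3 * grid$yc[5] - grid$zc[2])
  interior <- data.frame(x = 1.23, y = 2.71, z = 1.07)
  expect_equal(sample_at(lin, grid, interior),
               2 * 1.23 + 3 * 2.71 - 1.07, tolerance = 1e-10)
  expect_error(sample_at(uni, grid, data.frame(x = 3.5, y = 1, z = 1)),
               "outside the room")
})

test_that("steady activity balance closes in both source modes", {
  run <- small_room_run()
  src <- source_spec()
  for (mode in c("boundary_flux", "volumetric")) {
    rn <- solve_radon(run$grid, run$flow, src, mode)
    bal <- radon_balance(rn, run$grid, run$flow)
    expect_lt(abs(bal$relative), 1e-4)
    expect_true(all(rn$concentration >= 0))
  }
})

test_that("floor-adjacent layer exceeds the volume average with wall sources", {
  run <- small_room_run()
  rn <- solve_radon(run$grid, run$flow, source_spec(), "boundary_flux")
  floor_mean <- mean(rn$concentration[, , run$grid$zc < 0.3])
  expect_gt(floor_mean, rn$volume_average)
})

test_that("volume average decreases strictly with the ventilation rate", {
  geom <- room_geometry()
  grid <- generate_grid(geom, 4)
  air <- air_properties()
  G <- calibrated_G()
  avgs <- vapply(c(0.3, 0.5, 1, 1.5, 2, 4.3), function(a) {
    flow <- solve_flow(grid, ventilation_spec(a, geom), air,
                       solver_settings(max_iterations = 6000))
    solve_radon(grid, flow, source_spec(), "volumetric", G = G)$volume_average
  }, numeric(1))
  expect_true(all(diff(avgs) < 0))
})

test_that("manufactured-solution error decreases at first order or better", {
  src <- source_spec(exhalation = 0, c_out = 0, decay_constant = 1e-3,
                     diffusion = 0.01)
  errs <- vapply(c(16, 32), function(n) {
    geom <- room_geometry(1, 1, 1,
                          window = rect_patch("x1", c(0.5, 0.5), 0.2, 0.2),
                          door = rect_patch("y0", c(0.5, 0.4), 0.2, 0.8))
    grid <- generate_grid(geom, n)
    cs <- manufactured_case(grid, src, u0 = 1)
    solve_manufactured(grid, cs)$l2_error
  }, numeric(1))
  expect_gte(errs[1] / errs[2], 1.8)
})
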