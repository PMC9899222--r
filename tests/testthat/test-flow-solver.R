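test_that("no forcing gives the zero solution", {
  geom <- room_geometry()
  grid <- generate_grid(geom, 4)
  f <- solve_flow(grid, ventilation_spec(0, geom), air_properties(),
                  solver_settings(max_iterations = 100))
  expect_equal(max(abs(f$u)), 0)
  expect_equal(max(abs(f$v)), 0)
  expect_equal(max(abs(f$w)), 0)
  expect_equal(diff(range(f$pressure)), 0)
})

test_that("converged room flow satisfies continuity and global mass balance", {
  for (closure in c("constant_nu_eff", "k_epsilon")) {
    run <- small_room_run("closed", 4, 1, closure)
    expect_true(run$flow$converged)
    cc <- check_continuity(run$flow, run$grid)
    expect_lt(cc$max_scaled, 1e-5)
    expect_lt(abs(cc$mass_imbalance), 1e-6)
  }
})

test_that("divergence report matches an independent finite-difference oracle", {
  grid <- radonroom:::grid_box(1, 1, 1, 5, 5, 5)
  set.seed(42)
  f <- list(u = array(rnorm(6 * 5 * 5), c(6, 5, 5)),
            v = array(rnorm(5 * 6 * 5), c(5, 6, 5)),
            w = array(rnorm(5 * 5 * 6), c(5, 5, 6)),
            air = air_properties())
  cc <- check_continuity(f, grid)
  # oracle: loop-based conservative divergence, written independently
  Ax <- grid$dy * grid$dz; Ay <- grid$dx * grid$dz; Az <- grid$dx * grid$dy
  oracle <- array(0, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    oracle[i, j, k] <- f$air$density *
      (Ax * (f$u[i + 1, j, k] - f$u[i, j, k]) +
       Ay * (f$v[i, j + 1, k] - f$v[i, j, k]) +
       Az * (f$w[i, j, k + 1] - f$w[i, j, k]))
  }
  expect_equal(cc$divergence, oracle, tolerance = 1e-12)
  expect_gt(cc$max_scaled, 0)
})

test_that("solution is mirror-symmetric for a symmetric configuration", {
  grid <- radonroom:::grid_box(1, 1, 1, 8, 8, 8)
  grid$tags$x0[4:5, 4:5] <- radonroom:::TAG_INLET
  grid$tags$x1[4:5, 4:5] <- radonroom:::TAG_OUTLET
  vent <- ventilation_spec(1, room_volume = 1, vent_area = 4 / 64)
  f <- solve_flow(grid, vent, air_properties(),
                  solver_settings(max_iterations = 5000))
  scale <- max(abs(f$u))
  expect_lt(max(abs(f$u - f$u[, 8:1, ])) / scale, 1e-4)
  expect_lt(max(abs(f$v + f$v[, 9:1, ])) / scale, 1e-4)
  expect_lt(max(abs(f$w - f$w[, 8:1, ])) / scale, 1e-4)
})

test_that("lid-driven cavity matches the published centreline profile", {
  cv <- cavity_benchmark(n = 64, re = 100, max_iterations = 20000)
  # Ghia, Ghia & Shin (1982), Re = 100, u on the vertical centreline
  ref <- data.frame(z = c(0.1719, 0.2813, 0.4531, 0.5000, 0.8516),
                    u = c(-0.10150, -0.15662, -0.21090, -0.20581, 0.23151))
  ui <- stats::approx(cv$u_centerline$z, cv$u_centerline$u, ref$z)$y
  expect_true(all(abs(ui - ref$u) / abs(ref$u) < 0.05))
})

test_that("k-epsilon with no production decays k monotonically", {
  n <- 6
  grid <- radonroom:::grid_box(1, 1, 1, n, n, n, radonroom:::TAG_SLIP)
  f <- structure(list(
    u = array(0, c(n + 1, n, n)), v = array(0, c(n, n + 1, n)),
    w = array(0, c(n, n, n + 1)),
    k = array(0.01, c(n, n, n)), epsilon = array(0.005, c(n, n, n)),
    mut = array(1e-4, c(n, n, n)), inlet_speed = 0,
    air = air_properties()), class = "flow_field")
  ks <- mean(f$k)
  cur <- f
  for (i in 1:4) {
    cur <- k_epsilon_step(cur, grid, solver_settings(), air_properties())
    ks <- c(ks, mean(cur$k))
    expect_true(all(cur$k > 0))
    expect_true(all(cur$epsilon > 0))
    expect_true(all(cur$mut >= 0))
  }
  expect_true(all(diff(ks) < 0))
  bad <- f; bad$epsilon[1] <- 0
  expect_error(k_epsilon_step(bad, grid), "epsilon > 0")
})

test_that("flow solver errors carry the residual history on non-convergence", {
  geom <- room_geometry()
  grid <- generate_grid(geom, 4)
  err <- tryCatch(
    solve_flow(grid, ventilation_spec(1, geom), air_properties(),
               solver_settings(tolerance = 1e-14, max_iterations = 12)),
    error = function(e) e)
  expect_s3_class(err, "radonroom_no_convergence")
  expect_true(is.matrix(err$residual_history))
})
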