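test_that("reference room fixture matches the study configuration", {
  rr <- reference_room("open")
  expect_equal(rr$geom$volume, 33.6)
  expect_equal(rr$vent$vent_area, 0.96)
  expect_equal(rr$src$exhalation[["z0"]], 3.1)
  expect_equal(rr$src$c_out, 10)
  expect_equal(nrow(rr$points), 15)
  expect_setequal(unique(rr$points$point), c("A", "B", "C", "D", "Center"))
  expect_setequal(unique(rr$points$z), c(0.2, 1.0, 1.8))
  a <- rr$points[rr$points$point == "A", ][1, ]
  expect_equal(c(a$x, a$y), c(2.9, 0.1))
  expect_setequal(names(rr$measurements),
                  c("AlphaGUARD", "RAD7", "Raduet", "NRPB", "Simulation"))
})

test_that("manufactured velocity is discretely divergence-free", {
  geom <- room_geometry(1, 1, 1,
                        window = rect_patch("x1", c(0.5, 0.5), 0.2, 0.2),
                        door = rect_patch("y0", c(0.5, 0.4), 0.2, 0.8))
  grid <- generate_grid(geom, 12)
  cs <- manufactured_case(grid, source_spec(diffusion = 0.01), u0 = 1)
  fake <- list(u = cs$u, v = cs$v, w = cs$w, air = air_properties())
  cc <- check_continuity(fake, grid)
  # compare the raw divergence to the typical face flux u0 * A
  flux_scale <- air_properties()$density * 1 * grid$dy * grid$dz
  expect_lt(max(abs(cc$divergence)) / flux_scale, 1e-12)
})

test_that("degenerate manufactured cases reduce to the decay identity", {
  geom <- room_geometry(1, 1, 1,
                        window = rect_patch("x1", c(0.5, 0.5), 0.2, 0.2),
                        door = rect_patch("y0", c(0.5, 0.4), 0.2, 0.8))
  grid <- generate_grid(geom, 5)
  lam <- 2.5e-3
  src <- source_spec(decay_constant = lam, diffusion = 0.01)
  cs <- manufactured_case(grid, src, u0 = 0, c_mean = 40, c_amp = 0)
  expect_equal(range(cs$source), c(lam * 40, lam * 40))
  expect_equal(range(cs$exact_cells), c(40, 40))
  cz <- manufactured_case(grid, src, u0 = 0, c_mean = 0, c_amp = 0)
  expect_equal(max(abs(cz$source)), 0)
})

test_that("synthetic measurements are seed-reproducible and honest at sigma 0", {
  run <- small_room_run()
  rn <- solve_radon(run$grid, run$flow, source_spec(), "boundary_flux")
  pts <- detector_points()
  exact <- synthetic_measurements(rn, run$grid, pts, noise_model(sigma = 0))
  expect_equal(exact$records$concentration,
               sample_at(rn, run$grid, pts[, c("x", "y", "z")]))
  a <- synthetic_measurements(rn, run$grid, pts, noise_model(sigma = 0.2, seed = 5))
  b <- synthetic_measurements(rn, run$grid, pts, noise_model(sigma = 0.2, seed = 5))
  expect_identical(a$records, b$records)
  d <- synthetic_measurements(rn, run$grid, pts, noise_model(sigma = 0.2, seed = 6))
  expect_false(identical(a$records$concentration, d$records$concentration))
  # global RNG state is preserved
  set.seed(123); before <- .Random.seed
  synthetic_measurements(rn, run$grid, pts, noise_model(sigma = 0.2, seed = 5))
  expect_identical(.Random.seed, before)
})
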