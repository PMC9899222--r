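test_that("inlet velocity follows ACH * V / (A * 3600)", {
  expect_equal(inlet_velocity(1, 33.6, 0.96), 33.6 / 0.96 / 3600)
  expect_equal(round(inlet_velocity(1, 33.6, 0.96), 2), 0.01)
  expect_equal(inlet_velocity(0, 33.6, 0.96), 0)
  expect_equal(inlet_velocity(4.3, 33.6, 0.96), 0.0418, tolerance = 1e-3)
  # linear in ach and volume, inverse in area
  expect_equal(inlet_velocity(2, 33.6, 0.96), 2 * inlet_velocity(1, 33.6, 0.96))
  expect_equal(inlet_velocity(1, 67.2, 0.96), 2 * inlet_velocity(1, 33.6, 0.96))
  expect_equal(inlet_velocity(1, 33.6, 1.92), inlet_velocity(1, 33.6, 0.96) / 2)
  expect_error(inlet_velocity(1, 33.6, 0), "vent_area")
})

test_that("dry air density matches the ideal-gas oracle", {
  air <- air_properties(24, 0, 101325)
  expect_equal(air$density, 101325 / (287.058 * 297.15), tolerance = 1e-6)
  expect_equal(air$density, 1.188, tolerance = 1e-3)
  expect_gt(air$dynamic_viscosity, 1.7e-5)
  expect_lt(air$dynamic_viscosity, 1.95e-5)
})

test_that("density decreases with humidity and temperature", {
  rhs <- seq(0, 1, by = 0.1)
  dens <- vapply(rhs, function(r) air_properties(24, r)$density, numeric(1))
  expect_true(all(diff(dens) < 0))
  # full saturation is the minimum over RH at fixed T, P
  expect_equal(which.min(dens), length(rhs))
  temps <- seq(0, 40, by = 5)
  dt <- vapply(temps, function(tt) air_properties(tt, 0.5)$density, numeric(1))
  expect_true(all(diff(dt) < 0))
  expect_error(air_properties(24, 1.2), "rh")
  expect_error(air_properties(90, 0.5), "temperature")
})

test_that("Reynolds number is rho U L / mu and linear in speed", {
  air <- air_properties()
  dh <- hydraulic_diameter(rect_patch("x1", c(2, 1.4), 1.2, 0.8))
  expect_equal(dh, 0.96)
  re <- reynolds_number(0.01, dh, air)
  expect_equal(re, air$density * 0.01 * dh / air$dynamic_viscosity)
  expect_gt(re, 580); expect_lt(re, 660)
  expect_equal(reynolds_number(0, dh, air), 0)
  expect_equal(reynolds_number(0.02, dh, air), 2 * re)
})
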