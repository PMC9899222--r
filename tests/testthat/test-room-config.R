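test_that("default geometry reproduces the reference room", {
  g <- room_geometry()
  expect_equal(c(g$Lx, g$Ly, g$Lz), c(3.0, 4.0, 2.8))
  expect_equal(g$volume, 33.6)
  expect_equal(g$window$area, 0.96)
  expect_equal(g$door$area, 2.2)
  expect_equal(build_room(NULL)$volume, 33.6)
})

test_that("patches exceeding their wall are rejected with the patch name", {
  expect_error(
    room_geometry(window = rect_patch("y0", c(1.5, 1.4), 5.0, 0.8)),
    "window")
  expect_error(
    room_geometry(door = rect_patch("y0", c(0.5, 1.6), 1.0, 3.3)),
    regexp = "door")
  expect_error(room_geometry(door_gap_height = 0), "door_gap_height")
})

test_that("config documents are validated and unknown keys rejected", {
  g <- build_room(list(room = list(Lx = 2.5), scenario = "open"))
  expect_equal(g$Lx, 2.5)
  expect_equal(g$scenario, "open")
  expect_error(build_room(list(walls = list())), "unknown config section")
  expect_error(build_room(list(room = list(LX = 3))), "unknown key")
})

test_that("grid cell counts and exact volume partition", {
  g <- room_geometry()
  grid <- generate_grid(g, 10)
  expect_equal(c(grid$nx, grid$ny, grid$nz), c(30L, 40L, 28L))
  expect_equal(grid$nx * grid$ny * grid$nz, 33600L)
  for (res in c(4, 7, 10)) {
    gr <- generate_grid(g, res)
    expect_equal(gr$cell_volume * gr$nx * gr$ny * gr$nz, g$volume,
                 tolerance = 1e-12)
  }
  expect_error(generate_grid(g, 1), "at least 4 cells")
})

test_that("boundary tagging follows the scenario", {
  g_closed <- room_geometry(scenario = "closed")
  gr <- generate_grid(g_closed, 10)
  # window tagged inlet on x1, area exact at this resolution
  expect_equal(tagged_area(gr, "inlet"), 0.96)
  # closed door: only the under-door gap strip is an outlet
  expect_gt(tagged_area(gr, "pressure_outlet"), 0)
  expect_lt(tagged_area(gr, "pressure_outlet"), 0.5)
  # gap sits at the floor rows of the y0 wall
  expect_true(all(which(gr$tags$y0 == 2L, arr.ind = TRUE)[, 2] == 1))

  g_open <- room_geometry(scenario = "open")
  gro <- generate_grid(g_open, 10)
  expect_equal(tagged_area(gro, "pressure_outlet"), 2.2, tolerance = 0.15)
  # every boundary face carries exactly one tag (a valid code)
  for (w in names(gro$tags)) {
    expect_true(all(gro$tags[[w]] %in% c(0L, 1L, 2L)))
  }
})

test_that("tagging is deterministic and snapped areas converge", {
  g <- room_geometry()
  a <- generate_grid(g, 7)
  b <- generate_grid(g, 7)
  expect_identical(a$tags, b$tags)
  # first-order snapping bound: error at most one face strip per edge
  for (res in c(4, 6, 10)) {
    gr <- generate_grid(g, res)
    h <- max(gr$dy, gr$dz)
    expect_lte(abs(tagged_area(gr, "inlet") - g$window$area),
               2 * (g$window$width + g$window$height) * h)
  }
})

test_that("refinement series gives the expected grid sizes", {
  g <- room_geometry()
  grids <- refine_series(g, c(5, 10, 15))
  cells <- vapply(grids, function(x) x$nx * x$ny * x$nz, numeric(1))
  expect_equal(cells, c(4200, 33600, 113400))
  single <- refine_series(g, 10)
  expect_identical(single[[1]]$tags, generate_grid(g, 10)$tags)
  expect_error(refine_series(g, numeric(0)), "non-empty")
  expect_error(refine_series(g, c(10, 5)), "strictly increasing")
})
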