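#' Rectangular boundary patch on a room wall
#'
#' A rectangle lying in one of the six wall planes of the room box. The
#' in-wall coordinate pair is (y, z) for the `x0`/`x1` walls, (x, z) for
#' `y0`/`y1` and (x, y) for `z0`/`z1`.
#'
#' @param wall One of `"x0"`, `"x1"`, `"y0"`, `"y1"`, `"z0"`, `"z1"`.
#' @param center Numeric length-2: centre of the rectangle in the wall's
#'   in-plane coordinates (m).
#' @param width Extent along the first in-plane axis (m).
#' @param height Extent along the second in-plane axis (m).
#' @return An object of class `rect_patch`.
#' @export
rect_patch <- function(wall, center, width, height) {
  wall <- match.arg(wall, c("x0", "x1", "y0", "y1", "z0", "z1"))
  stopifnot(length(center) == 2, is.numeric(center))
  if (!(width > 0 && height > 0)) {
    stop("rect_patch: width and height must be positive")
  }
  structure(list(wall = wall, center = as.numeric(center),
                 width = width, height = height, area = width * height),
            class = "rect_patch")
}

patch_bounds <- function(p) {
  c(a_lo = p$center[1] - p$width / 2, a_hi = p$center[1] + p$width / 2,
    b_lo = p$center[2] - p$height / 2, b_hi = p$center[2] + p$height / 2)
}

# in-plane wall extents for a patch on a given wall
wall_extents <- function(wall, Lx, Ly, Lz) {
  switch(wall,
         x0 = , x1 = c(Ly, Lz),
         y0 = , y1 = c(Lx, Lz),
         z0 = , z1 = c(Lx, Ly))
}

#' Room geometry: box, window, door and scenario
#'
#' Defines the room as a rectangular box with one window (velocity inlet)
#' and one door. In the open-door scenario the whole door acts as a
#' pressure outlet; in the closed-door scenario only a thin under-door gap
#' does, and the rest of the door is a no-slip wall. The defaults are a
#' 3.0 x 4.0 x 2.8 m room (33.6 m^3) with a 1.2 x 0.8 m window centred on
#' the x = Lx wall and a 1.0 m x 2.2 m door on the y = 0 wall.
#'
#' @param Lx,Ly,Lz Room dimensions along x (width), y (length), z (height), m.
#' @param window A [rect_patch()] on a vertical wall; default 1.2 x 0.8 m
#'   centred on the `x1` wall.
#' @param door A [rect_patch()]; default 1.0 wide x 2.2 m tall on the `y0`
#'   wall, left edge 0.1 m from the corner, floor-flush.
#' @param door_gap_height Height (m) of the under-door gap that acts as a
#'   pressure outlet in both scenarios; default 0.03 m.
#' @param scenario `"open"` or `"closed"`.
#' @return An object of class `room_geometry`.
#' @export
room_geometry <- function(Lx = 3.0, Ly = 4.0, Lz = 2.8,
                          window = NULL, door = NULL,
                          door_gap_height = 0.03,
                          scenario = c("closed", "open")) {
  scenario <- match.arg(scenario)
  if (!(Lx > 0 && Ly > 0 && Lz > 0)) stop("room dimensions must be positive")
  if (is.null(window)) {
    window <- rect_patch("x1", c(Ly / 2, Lz / 2), 1.2, 0.8)
  }
  if (is.null(door)) {
    door <- rect_patch("y0", c(0.1 + 1.0 / 2, 2.2 / 2), 1.0, 2.2)
  }
  for (nm in c("window", "door")) {
    p <- if (nm == "window") window else door
    ext <- wall_extents(p$wall, Lx, Ly, Lz)
    b <- patch_bounds(p)
    if (b["a_lo"] < -1e-12 || b["a_hi"] > ext[1] + 1e-12 ||
        b["b_lo"] < -1e-12 || b["b_hi"] > ext[2] + 1e-12) {
      stop(sprintf("patch '%s' exceeds the extent of wall %s", nm, p$wall))
    }
  }
  if (!(door_gap_height > 0 && door_gap_height <= door$height)) {
    stop("door_gap_height must be in (0, door height]")
  }
  structure(list(Lx = Lx, Ly = Ly, Lz = Lz, window = window, door = door,
                 door_gap_height = door_gap_height, scenario = scenario,
                 volume = Lx * Ly * Lz),
            class = "room_geometry")
}

#' @export
print.room_geometry <- function(x, ...) {
  cat(sprintf("room %.2f x %.2f x %.2f m (V = %.2f m^3), scenario: %s\n",
              x$Lx, x$Ly, x$Lz, x$volume, x$scenario))
  cat(sprintf("  window %.2f x %.2f m on wall %s (area %.3f m^2)\n",
              x$window$width, x$window$height, x$window$wall, x$window$area))
  cat(sprintf("  door %.2f x %.2f m on wall %s, under-door gap %.3f m\n",
              x$door$width, x$door$height, x$door$wall, x$door_gap_height))
  invisible(x)
}

config_schema <- list(
  room = c("Lx", "Ly", "Lz"),
  window = c("width", "height", "center_y", "center_z"),
  door = c("width", "height", "x_left", "gap_height"),
  scenario = NULL,
  grid = c("resolution", "nx", "ny", "nz"),
  ventilation = c("ach"),
  air = c("temperature", "rh", "pressure"),
  source = c("exhalation", "c_out", "mode", "g", "decay_constant",
             "diffusion"),
  solver = c("closure", "tolerance", "max_iterations", "relax_momentum",
             "relax_pressure", "relax_turbulence", "advection", "nu_eff")
)

validate_config <- function(config) {
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in names(config)) {
    allowed <- config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) in config section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
    }
  }
  invisible(config)
}

#' Build a validated room geometry from a configuration
#'
#' @param config `NULL` (defaults), a named list, or the path of a
#'   YAML config file with sections `room`, `window`, `door`, `scenario`
#'   (plus `grid`, `ventilation`, `air`, `source`, `solver`, consumed by
#'   the pipeline). Unknown sections or keys are rejected.
#' @return A [room_geometry()].
#' @export
build_room <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  validate_config(config)
  rm_ <- config$room
  Lx <- rm_$Lx %||% 3.0; Ly <- rm_$Ly %||% 4.0; Lz <- rm_$Lz %||% 2.8
  win <- config$window
  window <- rect_patch("x1",
                       c(win$center_y %||% (Ly / 2), win$center_z %||% (Lz / 2)),
                       win$width %||% 1.2, win$height %||% 0.8)
  dr <- config$door
  dw <- dr$width %||% 1.0; dh <- dr$height %||% 2.2
  xl <- dr$x_left %||% 0.1
  door <- rect_patch("y0", c(xl + dw / 2, dh / 2), dw, dh)
  room_geometry(Lx, Ly, Lz, window = window, door = door,
                door_gap_height = dr$gap_height %||% 0.03,
                scenario = config$scenario %||% "closed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Boundary tag codes shared with the compiled solver.
TAG_WALL <- 0L
TAG_INLET <- 1L
TAG_OUTLET <- 2L
TAG_SLIP <- 3L
TAG_LID <- 4L

tag_names <- c(wall_noslip = TAG_WALL, inlet = TAG_INLET,
               pressure_outlet = TAG_OUTLET, slip = TAG_SLIP, lid = TAG_LID)

# Snap a 1-d interval [lo, hi] (m) onto face indices of an axis with n cells
# of spacing d. Guarantees at least one face strip for a non-empty interval.
snap_interval <- function(lo, hi, n, d) {
  i0 <- max(0L, min(n, as.integer(round(lo / d))))
  i1 <- max(0L, min(n, as.integer(round(hi / d))))
  if (i1 <= i0) {
    if (i0 >= n) i0 <- n - 1L
    i1 <- i0 + 1L
  }
  c(i0, i1) # 0-based face indices; cells i0+1 .. i1 in 1-based terms
}

apply_patch_tag <- function(tags, wall, bounds, grid, tag) {
  dims <- switch(wall,
                 x0 = , x1 = c(grid$ny, grid$nz, grid$dy, grid$dz),
                 y0 = , y1 = c(grid$nx, grid$nz, grid$dx, grid$dz),
                 z0 = , z1 = c(grid$nx, grid$ny, grid$dx, grid$dy))
  a <- snap_interval(bounds[1], bounds[2], dims[1], dims[3])
  b <- snap_interval(bounds[3], bounds[4], dims[2], dims[4])
  tags[[wall]][(a[1] + 1):a[2], (b[1] + 1):b[2]] <- tag
  tags
}

#' Generate a uniform structured Cartesian grid with boundary-patch tags
#'
#' Cells are uniform along each axis; the window and door rectangles are
#' snapped to the nearest cell-face boundaries (a patch always occupies at
#' least one face strip, so the thin under-door gap survives coarse grids
#' at the price of an inflated snapped area). Every boundary face carries
#' exactly one tag: `wall_noslip`, `inlet`, or `pressure_outlet`.
#'
#' @param geom A [room_geometry()].
#' @param resolution Either a scalar (cells per metre) or an integer vector
#'   `c(nx, ny, nz)`. At least 4 cells per axis are required.
#' @return An object of class `room_grid` with cell counts, spacings, cell
#'   centre coordinates and six boundary tag matrices.
#' @export
generate_grid <- function(geom, resolution = 10) {
  stopifnot(inherits(geom, "room_geometry"))
  if (length(resolution) == 1) {
    n <- c(round(geom$Lx * resolution), round(geom$Ly * resolution),
           round(geom$Lz * resolution))
  } else if (length(resolution) == 3) {
    n <- as.integer(resolution)
  } else stop("resolution must be a scalar or a length-3 vector")
  if (any(n < 4)) {
    stop("grid too coarse: need at least 4 cells per axis; increase resolution")
  }
  nx <- as.integer(n[1]); ny <- as.integer(n[2]); nz <- as.integer(n[3])
  dx <- geom$Lx / nx; dy <- geom$Ly / ny; dz <- geom$Lz / nz
  tags <- list(
    x0 = matrix(TAG_WALL, ny, nz), x1 = matrix(TAG_WALL, ny, nz),
    y0 = matrix(TAG_WALL, nx, nz), y1 = matrix(TAG_WALL, nx, nz),
    z0 = matrix(TAG_WALL, nx, ny), z1 = matrix(TAG_WALL, nx, ny))
  grid <- list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy, dz = dz,
               Lx = geom$Lx, Ly = geom$Ly, Lz = geom$Lz,
               xc = (seq_len(nx) - 0.5) * dx, yc = (seq_len(ny) - 0.5) * dy,
               zc = (seq_len(nz) - 0.5) * dz)

  # window: velocity inlet
  wb <- patch_bounds(geom$window)
  tags <- apply_patch_tag(tags, geom$window$wall, wb, grid, TAG_INLET)
  # door: outlet when open; wall + under-door gap outlet when closed
  db <- patch_bounds(geom$door)
  if (geom$scenario == "open") {
    tags <- apply_patch_tag(tags, geom$door$wall, db, grid, TAG_OUTLET)
  } else {
    gap <- c(db["a_lo"], db["a_hi"], 0, geom$door_gap_height)
    tags <- apply_patch_tag(tags, geom$door$wall, gap, grid, TAG_OUTLET)
  }
  grid$tags <- tags
  grid$geom <- geom
  grid$cell_volume <- dx * dy * dz
  structure(grid, class = "room_grid")
}

#' @export
print.room_grid <- function(x, ...) {
  cat(sprintf("structured grid %d x %d x %d (%d cells), spacing %.3g/%.3g/%.3g m\n",
              x$nx, x$ny, x$nz, x$nx * x$ny * x$nz, x$dx, x$dy, x$dz))
  cat(sprintf("  inlet area %.3f m^2, outlet area %.3f m^2\n",
              tagged_area(x, "inlet"), tagged_area(x, "pressure_outlet")))
  invisible(x)
}

#' Total boundary-face area carrying a given tag
#'
#' @param grid A `room_grid`.
#' @param tag `"wall_noslip"`, `"inlet"`, `"pressure_outlet"`, `"slip"` or
#'   `"lid"`.
#' @return Area in m^2.
#' @export
tagged_area <- function(grid, tag) {
  code <- tag_names[[tag]]
  areas <- c(x0 = grid$dy * grid$dz, x1 = grid$dy * grid$dz,
             y0 = grid$dx * grid$dz, y1 = grid$dx * grid$dz,
             z0 = grid$dx * grid$dy, z1 = grid$dx * grid$dy)
  sum(vapply(names(grid$tags), function(w) {
    sum(grid$tags[[w]] == code) * areas[[w]]
  }, numeric(1)))
}

#' Grid-refinement series for a convergence study
#'
#' @param geom A [room_geometry()].
#' @param levels Strictly increasing vector of resolutions (cells per metre).
#' @return List of `room_grid` objects, one per level.
#' @export
refine_series <- function(geom, levels) {
  if (length(levels) == 0) stop("refine_series: 'levels' must be non-empty")
  if (length(levels) > 1 && any(diff(levels) <= 0)) {
    stop("refine_series: 'levels' must be strictly increasing")
  }
  lapply(levels, function(l) generate_grid(geom, l))
}

# Internal: bare tagged box used by verification presets (cavity, channel).
grid_box <- function(Lx, Ly, Lz, nx, ny, nz, default_tag = TAG_WALL) {
  g <- list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
            dx = Lx / nx, dy = Ly / ny, dz = Lz / nz,
            Lx = Lx, Ly = Ly, Lz = Lz)
  g$xc <- (seq_len(nx) - 0.5) * g$dx
  g$yc <- (seq_len(ny) - 0.5) * g$dy
  g$zc <- (seq_len(nz) - 0.5) * g$dz
  g$tags <- list(x0 = matrix(default_tag, ny, nz), x1 = matrix(default_tag, ny, nz),
                 y0 = matrix(default_tag, nx, nz), y1 = matrix(default_tag, nx, nz),
                 z0 = matrix(default_tag, nx, ny), z1 = matrix(default_tag, nx, ny))
  g$cell_volume <- g$dx * g$dy * g$dz
  structure(g, class = "room_grid")
}
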