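#' The reference room study configuration
#'
#' Returns the full configuration of the measured test room: a
#' 3.0 x 4.0 x 2.8 m room (33.6 m^3) with a 1.2 x 0.8 m window and a
#' 1.0 x 2.2 m door, exhalation 3.1 Bq m^-2 h^-1 on all surfaces, outdoor
#' concentration 10 Bq m^-3, together with the detector grid (points A,
#' B, C, D and Center at heights 0.2, 1.0 and 1.8 m) and the published
#' detector/CFD comparison tables shipped as fixtures.
#'
#' @param scenario `"closed"` or `"open"`.
#' @param ach Air-change rate, h^-1 (default 1).
#' @return List with `geom`, `vent`, `src`, `points` (data.frame of the 15
#'   detector locations) and `measurements` (list of `measurement_set`
#'   objects read from the fixture CSV for the scenario).
#' @export
reference_room <- function(scenario = c("closed", "open"), ach = 1) {
  scenario <- match.arg(scenario)
  geom <- room_geometry(scenario = scenario)
  vent <- ventilation_spec(ach, geom)
  src <- source_spec()
  pts <- detector_points()
  f <- system.file("extdata", paste0("measurements_", scenario, ".csv"),
                   package = "radonroom")
  meas <- if (nzchar(f)) read_measurements(f) else list()
  list(geom = geom, vent = vent, src = src, points = pts,
       measurements = meas, scenario = scenario, ach = ach)
}

#' Detector sampling locations of the reference room
#'
#' Five plan positions (four corners 0.1 m from the walls plus the room
#' centre) at three heights (0.2, 1.0, 1.8 m).
#'
#' @return Data frame with columns `point`, `x`, `y`, `z` (m), 15 rows.
#' @export
detector_points <- function() {
  plan <- data.frame(point = c("A", "B", "C", "D", "Center"),
                     x = c(2.9, 0.1, 0.1, 2.9, 1.5),
                     y = c(0.1, 0.1, 3.9, 3.9, 2.0))
  heights <- c(0.2, 1.0, 1.8)
  out <- do.call(rbind, lapply(heights, function(h) {
    transform(plan, z = h)
  }))
  rownames(out) <- NULL
  out
}

#' Manufactured advection-diffusion-decay verification case
#'
#' Builds a discretely divergence-free trigonometric velocity field (from
#' a streamfunction evaluated at cell corners), a smooth closed-form
#' concentration field, and the source term that makes the closed form an
#' exact steady solution: `S = U.grad(C) - D lap(C) + lambda C`.
#' Dirichlet boundary values are taken from the exact field.
#'
#' @param grid A `room_grid` (any tagged box; tags are ignored).
#' @param params A [source_spec()] supplying `diffusion` and
#'   `decay_constant`.
#' @param u0 Velocity amplitude (m s^-1).
#' @param c_mean,c_amp Mean and amplitude of the exact concentration.
#' @return Object of class `manufactured_case` with face velocity arrays,
#'   the exact solution (function and cell array), the per-cell source and
#'   Dirichlet boundary values.
#' @export
manufactured_case <- function(grid, params = source_spec(), u0 = 1,
                              c_mean = 100, c_amp = 50) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  a <- pi / grid$Lx; b <- pi / grid$Ly; cc <- pi / grid$Lz
  psi <- function(x, y) (u0 / b) * sin(a * x) * sin(b * y)
  xf <- (0:nx) * grid$dx; yf <- (0:ny) * grid$dy; zf <- (0:nz) * grid$dz
  xc <- grid$xc; yc <- grid$yc; zc <- grid$zc

  # u at x-faces: difference of the streamfunction over cell corners in y
  u <- array(0, c(nx + 1, ny, nz))
  for (j in seq_len(ny)) {
    u[, j, ] <- (psi(xf, yf[j + 1]) - psi(xf, yf[j])) / grid$dy
  }
  v <- array(0, c(nx, ny + 1, nz))
  for (jf in seq_len(ny + 1)) {
    v[, jf, ] <- -(psi(xf[2:(nx + 1)], yf[jf]) - psi(xf[1:nx], yf[jf])) / grid$dx
  }
  w <- array(0, c(nx, ny, nz + 1))

  exact <- function(x, y, z) {
    c_mean + c_amp * cos(a * x) * cos(b * y) * cos(cc * z)
  }
  D <- params$diffusion; lam <- params$decay_constant
  source_fun <- function(x, y, z) {
    cx <- -c_amp * a * sin(a * x) * cos(b * y) * cos(cc * z)
    cy <- -c_amp * b * cos(a * x) * sin(b * y) * cos(cc * z)
    cz <- -c_amp * cc * cos(a * x) * cos(b * y) * sin(cc * z)
    ue <- u0 * sin(a * x) * cos(b * y)
    ve <- -u0 * (a / b) * cos(a * x) * sin(b * y)
    lap <- -(a^2 + b^2 + cc^2) * (exact(x, y, z) - c_mean)
    ue * cx + ve * cy - D * lap + lam * exact(x, y, z)
  }
  mesh <- function(f, x, y, z) {
    outer3 <- array(0, c(length(x), length(y), length(z)))
    for (k in seq_along(z)) outer3[, , k] <- outer(x, y, function(px, py) f(px, py, z[k]))
    outer3
  }
  exact_cells <- mesh(exact, xc, yc, zc)
  source_cells <- mesh(source_fun, xc, yc, zc)
  bvals <- list(
    x0 = outer(yc, zc, function(py, pz) exact(0, py, pz)),
    x1 = outer(yc, zc, function(py, pz) exact(grid$Lx, py, pz)),
    y0 = outer(xc, zc, function(px, pz) exact(px, 0, pz)),
    y1 = outer(xc, zc, function(px, pz) exact(px, grid$Ly, pz)),
    z0 = outer(xc, yc, function(px, py) exact(px, py, 0)),
    z1 = outer(xc, yc, function(px, py) exact(px, py, grid$Lz)))
  structure(list(u = u, v = v, w = w, exact = exact,
                 exact_cells = exact_cells, source = source_cells,
                 boundary_values = bvals, diffusion = D,
                 decay_constant = lam),
            class = "manufactured_case")
}

#' Solve a manufactured case and report the discrete L2 error
#'
#' Runs the same conservative upwind finite-volume discretization used
#' for radon on the manufactured velocity/source pair with Dirichlet
#' boundaries from the exact field.
#'
#' @param grid The `room_grid` the case was built on.
#' @param case A [manufactured_case()].
#' @return List with the numerical `concentration` array, the exact cell
#'   values and `l2_error` (root-mean-square cell error).
#' @export
solve_manufactured <- function(grid, case) {
  gamma <- array(case$diffusion, c(grid$nx, grid$ny, grid$nz))
  bc <- lapply(case$boundary_values, function(vmat) {
    list(type = "dirichlet", value = c(vmat))
  })
  sys <- assemble_scalar_system(grid, case$u, case$v, case$w, gamma,
                                case$decay_constant, case$source, bc)
  conc <- array(as.numeric(Matrix::solve(sys$A, sys$b)),
                c(grid$nx, grid$ny, grid$nz))
  list(concentration = conc, exact = case$exact_cells,
       l2_error = sqrt(mean((conc - case$exact_cells)^2)))
}

#' Measurement noise model
#'
#' @param kind `"multiplicative_lognormal"` (mean-one lognormal factor,
#'   sigma as a fraction) or `"additive_gaussian"` (sigma in Bq m^-3).
#' @param sigma Noise scale, >= 0.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative_lognormal",
                                 "additive_gaussian"),
                        sigma = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("noise_model: sigma must be non-negative")
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate synthetic detector readings from a ground-truth field
#'
#' Samples the truth at the requested points and perturbs the samples with
#' the noise model. All randomness flows through the model's seed; the
#' global RNG state is left untouched.
#'
#' @param truth A `radon_field`, a 3-d cell array, or a function
#'   `f(x, y, z)`.
#' @param grid The `room_grid` (ignored when `truth` is a function).
#' @param points Matrix or data.frame of (x, y, z) coordinates in metres.
#' @param noise A [noise_model()].
#' @return A `measurement_set` with device `"synthetic"`.
#' @export
synthetic_measurements <- function(truth, grid, points,
                                   noise = noise_model()) {
  pts <- as.data.frame(coordinate_matrix(points))
  names(pts) <- c("x", "y", "z")
  if (is.data.frame(points) && "point" %in% names(points)) {
    pts$point <- points$point
  }
  base <- if (is.function(truth)) {
    truth(pts$x, pts$y, pts$z)
  } else {
    sample_at(truth, grid, pts)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(noise$seed)
  n <- length(base)
  noisy <- switch(noise$kind,
    multiplicative_lognormal =
      base * exp(noise$sigma * stats::rnorm(n) - noise$sigma^2 / 2),
    additive_gaussian = base + noise$sigma * stats::rnorm(n))
  noisy <- pmax(noisy, 0)
  rec <- data.frame(x = pts$x, y = pts$y, z = pts$z, concentration = noisy)
  if ("point" %in% names(pts)) rec$point <- pts$point
  measurement_set("synthetic", rec)
}
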