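#' Solver settings for the flow and scalar-transport solvers
#'
#' @param closure Viscosity closure: `"constant_nu_eff"` (a single
#'   effective kinematic viscosity, molecular plus an inlet-scale
#'   turbulent estimate) or `"k_epsilon"` (standard k-epsilon with
#'   log-law wall functions).
#' @param tolerance Convergence tolerance on the relative change of the
#'   velocity field between consecutive outer iterations (default 1e-6).
#' @param max_iterations Maximum SIMPLE outer iterations.
#' @param relax_momentum,relax_pressure,relax_turbulence Under-relaxation
#'   factors in (0, 1].
#' @param advection `"hybrid"` (central/upwind blend) or `"upwind"`.
#' @param nu_eff Effective kinematic viscosity (m^2 s^-1) for the
#'   `constant_nu_eff` closure; `NULL` derives it from the inlet
#'   turbulence estimate (5\% intensity, length scale 0.07 x window
#'   hydraulic diameter).
#' @param turb_intensity,turb_length_frac Inlet turbulence intensity and
#'   length-scale fraction of the hydraulic diameter.
#' @return Object of class `solver_settings`.
#' @export
solver_settings <- function(closure = c("constant_nu_eff", "k_epsilon"),
                            tolerance = 1e-6, max_iterations = 5000,
                            relax_momentum = 0.7, relax_pressure = 0.3,
                            relax_turbulence = 0.5,
                            advection = c("hybrid", "upwind"),
                            nu_eff = NULL, turb_intensity = 0.05,
                            turb_length_frac = 0.07) {
  closure <- match.arg(closure)
  advection <- match.arg(advection)
  stopifnot(tolerance > 0,
            relax_momentum > 0, relax_momentum <= 1,
            relax_pressure > 0, relax_pressure <= 1,
            relax_turbulence > 0, relax_turbulence <= 1)
  structure(list(closure = closure, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 relax_momentum = relax_momentum,
                 relax_pressure = relax_pressure,
                 relax_turbulence = relax_turbulence,
                 advection = advection, nu_eff = nu_eff,
                 turb_intensity = turb_intensity,
                 turb_length_frac = turb_length_frac),
            class = "solver_settings")
}

# inlet turbulence estimates used for initial/boundary k, epsilon and for
# the constant effective viscosity
inlet_turbulence <- function(uin, length_scale, settings) {
  kin <- 1.5 * (settings$turb_intensity * uin)^2
  l <- settings$turb_length_frac * length_scale
  if (l <= 0) l <- 1e-3
  epsin <- 0.09^0.75 * max(kin, 1e-14)^1.5 / l
  nut <- 0.09^0.25 * sqrt(max(kin, 0)) * l
  list(k = max(kin, 1e-14), epsilon = max(epsin, 1e-20), nut = nut, l = l)
}

as_field_array <- function(x, dims) {
  array(as.numeric(x), dim = dims)
}

#' Solve the steady incompressible room airflow
#'
#' SIMPLE pressure-velocity coupling on the staggered grid: uniform normal
#' velocity on the window (inlet) patch, zero-gradient globally
#' mass-balanced outflow on the pressure-outlet patch(es), and no-slip on
#' the remaining surfaces. The inlet speed is set so that the volumetric
#' inflow equals `ACH * V_room / 3600` exactly on the snapped inlet patch.
#' Convergence is declared when the relative change of the velocity field
#' between two consecutive iterations drops below `settings$tolerance`.
#'
#' @param grid A `room_grid` from [generate_grid()].
#' @param vent A [ventilation_spec()].
#' @param air An [air_properties()] object.
#' @param settings A [solver_settings()] object.
#' @param verbose Print residual summaries every 100 iterations.
#' @return An object of class `flow_field`: staggered face velocities `u`,
#'   `v`, `w` (m s^-1), cell `pressure` (Pa, relative), turbulence fields
#'   `k`, `epsilon`, `mut`, the residual history and convergence metadata.
#' @export
solve_flow <- function(grid, vent, air = air_properties(),
                       settings = solver_settings(), verbose = FALSE) {
  stopifnot(inherits(grid, "room_grid"))
  a_in <- tagged_area(grid, "inlet")
  a_out <- tagged_area(grid, "pressure_outlet")
  q_target <- vent$ach * vent$room_volume / 3600 # m^3 s^-1
  if (q_target > 0 && a_in <= 0) {
    stop("solve_flow: positive ventilation but no inlet faces tagged")
  }
  if (q_target > 0 && a_out <= 0) {
    stop("solve_flow: no pressure-outlet faces tagged; flow cannot leave")
  }
  uin <- if (a_in > 0) q_target / a_in else 0
  lscale <- if (!is.null(grid$geom)) hydraulic_diameter(grid$geom$window) else
    min(grid$Lx, grid$Ly, grid$Lz)
  turb <- inlet_turbulence(uin, lscale, settings)
  nu_mol <- air$dynamic_viscosity / air$density
  nu_eff <- settings$nu_eff %||% (nu_mol + turb$nut)

  res <- simple_solve_cpp(
    grid$nx, grid$ny, grid$nz, grid$dx, grid$dy, grid$dz,
    grid$tags$x0, grid$tags$x1, grid$tags$y0, grid$tags$y1,
    grid$tags$z0, grid$tags$z1,
    uin, 0.0, air$density, air$dynamic_viscosity, nu_eff,
    ifelse(settings$closure == "k_epsilon", 1L, 0L),
    ifelse(settings$advection == "upwind", 0L, 1L),
    settings$tolerance, settings$max_iterations,
    settings$relax_momentum, settings$relax_pressure,
    settings$relax_turbulence, turb$k, turb$epsilon, verbose)

  field <- flow_field_from_cpp(res, grid, air, settings, uin)
  if (!field$converged) {
    cond <- structure(
      class = c("radonroom_no_convergence", "error", "condition"),
      list(message = sprintf(
        "flow solver did not reach tolerance %.1e in %d iterations (last delta %.3e)",
        settings$tolerance, settings$max_iterations,
        utils::tail(field$residual_history[, "delta"], 1)),
        call = sys.call(), residual_history = field$residual_history))
    stop(cond)
  }
  field
}

flow_field_from_cpp <- function(res, grid, air, settings, uin) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  structure(list(
    u = as_field_array(res$u, c(nx + 1, ny, nz)),
    v = as_field_array(res$v, c(nx, ny + 1, nz)),
    w = as_field_array(res$w, c(nx, ny, nz + 1)),
    pressure = as_field_array(res$p, c(nx, ny, nz)),
    k = as_field_array(res$k, c(nx, ny, nz)),
    epsilon = as_field_array(res$epsilon, c(nx, ny, nz)),
    mut = as_field_array(res$mut, c(nx, ny, nz)),
    residual_history = res$residuals,
    iterations = res$iterations,
    converged = res$converged,
    inlet_speed = uin, air = air, settings = settings),
    class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow field: %s after %d iterations (inlet %.4g m/s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$inlet_speed))
  mb <- attr(x, "mass_balance")
  invisible(x)
}

#' Discrete continuity check
#'
#' Computes the per-cell divergence of the staggered velocity field,
#' scaled by the inlet mass flux (or the maximum face flux when there is
#' no through-flow).
#'
#' @param field A `flow_field`.
#' @param grid The `room_grid` the field was solved on.
#' @return List with `max_scaled`, `rms_scaled`, the raw per-cell
#'   divergence array (kg s^-1) and the global `mass_imbalance`
#'   (inlet minus outlet mass flux, relative to the inlet flux).
#' @export
check_continuity <- function(field, grid) {
  rho <- field$air$density %||% 1
  div <- divergence_array(field, grid, rho)
  fluxes <- boundary_fluxes(field, grid, rho)
  scale <- max(fluxes$inflow, max(abs(div)), 1e-300)
  list(max_scaled = max(abs(div)) / scale,
       rms_scaled = sqrt(mean(div^2)) / scale,
       divergence = div,
       mass_imbalance = (fluxes$inflow - fluxes$outflow) /
         max(fluxes$inflow, 1e-300))
}

divergence_array <- function(field, grid, rho = 1) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  Ax <- grid$dy * grid$dz; Ay <- grid$dx * grid$dz; Az <- grid$dx * grid$dy
  u <- field$u; v <- field$v; w <- field$w
  rho * (Ax * (u[2:(nx + 1), , , drop = FALSE] - u[1:nx, , , drop = FALSE]) +
         Ay * (v[, 2:(ny + 1), , drop = FALSE] - v[, 1:ny, , drop = FALSE]) +
         Az * (w[, , 2:(nz + 1), drop = FALSE] - w[, , 1:nz, drop = FALSE]))
}

# total inflow/outflow mass fluxes through tagged boundary faces
boundary_fluxes <- function(field, grid, rho = 1) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  Ax <- grid$dy * grid$dz; Ay <- grid$dx * grid$dz; Az <- grid$dx * grid$dy
  inflow <- 0; outflow <- 0
  add <- function(vn, area) {
    # vn: outward-positive normal velocity matrix on a boundary plane
    inflow <<- inflow + sum(pmax(-vn, 0) * area * rho)
    outflow <<- outflow + sum(pmax(vn, 0) * area * rho)
  }
  add(-field$u[1, , ], Ax)           # x0: outward is -x
  add(field$u[nx + 1, , ], Ax)       # x1
  add(-field$v[, 1, ], Ay)
  add(field$v[, ny + 1, ], Ay)
  add(-field$w[, , 1], Az)
  add(field$w[, , nz + 1], Az)
  list(inflow = inflow, outflow = outflow)
}

#' One k-epsilon transport update on a frozen velocity field
#'
#' Performs a single under-relaxed update of the turbulent kinetic energy,
#' its dissipation rate, and the turbulent viscosity
#' `mut = rho * Cmu * k^2 / epsilon`, using the standard constants
#' (Cmu 0.09, C1 1.44, C2 1.92, sigma_k 1.0, sigma_eps 1.3) and log-law
#' wall functions in wall-adjacent cells.
#'
#' @param field A `flow_field` (its `u`, `v`, `w`, `k`, `epsilon`, `mut`
#'   are used as the current state).
#' @param grid The `room_grid`.
#' @param settings A [solver_settings()]; `relax_turbulence` is honoured.
#' @param air An [air_properties()] object.
#' @return The `flow_field` with updated `k`, `epsilon` and `mut`.
#' @export
k_epsilon_step <- function(field, grid, settings = solver_settings(),
                           air = air_properties()) {
  if (any(field$k < 0) || any(field$epsilon <= 0)) {
    stop("k_epsilon_step: requires k >= 0 and epsilon > 0")
  }
  lscale <- if (!is.null(grid$geom)) hydraulic_diameter(grid$geom$window) else
    min(grid$Lx, grid$Ly, grid$Lz)
  turb <- inlet_turbulence(field$inlet_speed %||% 0, lscale, settings)
  res <- keps_step_cpp(
    grid$nx, grid$ny, grid$nz, grid$dx, grid$dy, grid$dz,
    grid$tags$x0, grid$tags$x1, grid$tags$y0, grid$tags$y1,
    grid$tags$z0, grid$tags$z1,
    as.numeric(field$u), as.numeric(field$v), as.numeric(field$w),
    as.numeric(field$k), as.numeric(field$epsilon), as.numeric(field$mut),
    air$density, air$dynamic_viscosity, settings$relax_turbulence,
    turb$k, turb$epsilon,
    ifelse(settings$advection == "upwind", 0L, 1L), 4L)
  dims <- c(grid$nx, grid$ny, grid$nz)
  if (any(!is.finite(res$k)) || any(!is.finite(res$epsilon))) {
    stop("k_epsilon_step: non-finite turbulence quantities after update")
  }
  field$k <- as_field_array(res$k, dims)
  field$epsilon <- as_field_array(res$epsilon, dims)
  field$mut <- as_field_array(res$mut, dims)
  field
}

#' Lid-driven cavity verification preset
#'
#' Solves the classic square lid-driven cavity at a given Reynolds number
#' with the constant-viscosity closure, as a quasi-2D (single cell in y,
#' free-slip side walls) configuration in the x-z plane. The lid is the
#' top (`z1`) wall moving in +x at unit speed.
#'
#' @param n Cells per side.
#' @param re Reynolds number (lid speed 1, cavity side 1).
#' @param tolerance,max_iterations Solver controls.
#' @return A list with the `grid`, the `flow_field`, and `u_centerline`:
#'   a data.frame of z-coordinates and x-velocity at the vertical
#'   centreline (x = 0.5), cell-centred.
#' @export
cavity_benchmark <- function(n = 64, re = 100, tolerance = 1e-6,
                             max_iterations = 20000) {
  grid <- grid_box(1, 1 / n, 1, n, 1, n)
  grid$tags$y0[] <- TAG_SLIP
  grid$tags$y1[] <- TAG_SLIP
  grid$tags$z1[] <- TAG_LID
  settings <- solver_settings(closure = "constant_nu_eff",
                              tolerance = tolerance,
                              max_iterations = max_iterations,
                              nu_eff = 1 / re)
  res <- simple_solve_cpp(
    grid$nx, grid$ny, grid$nz, grid$dx, grid$dy, grid$dz,
    grid$tags$x0, grid$tags$x1, grid$tags$y0, grid$tags$y1,
    grid$tags$z0, grid$tags$z1,
    0.0, 1.0, 1.0, 1 / re, 1 / re, 0L, 1L,
    tolerance, as.integer(max_iterations), 0.7, 0.3, 0.5,
    1e-14, 1e-20, FALSE)
  air <- structure(list(density = 1, dynamic_viscosity = 1 / re),
                   class = "air_properties")
  field <- flow_field_from_cpp(res, grid, air, settings, 0)
  if (!field$converged) stop("cavity benchmark did not converge")
  # u at the vertical centreline: average the two u-faces nearest x = 0.5
  iu <- n %/% 2 + 1 # face at x = 0.5 for even n
  ucl <- field$u[iu, 1, ]
  list(grid = grid, field = field,
       u_centerline = data.frame(z = grid$zc, u = ucl))
}
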