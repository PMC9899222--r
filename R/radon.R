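#' Radon source specification
#'
#' Per-surface exhalation rates, outdoor concentration and the physical
#' constants of the transport equation. Defaults: exhalation 3.1
#' Bq m^-2 h^-1 on every surface (measured for cement), outdoor
#' concentration 10 Bq m^-3, decay constant 2.1e-6 s^-1 and molecular
#' diffusion coefficient of radon in air 1.2e-5 m^2 s^-1.
#'
#' @param exhalation Either a single rate applied to all six surfaces or a
#'   named vector with entries among `x0`, `x1`, `y0`, `y1`, `z0`
#'   (floor), `z1` (ceiling), in Bq m^-2 h^-1.
#' @param c_out Outdoor radon concentration (Bq m^-3), used as the inlet
#'   advected value.
#' @param decay_constant Radon-222 decay constant (s^-1).
#' @param diffusion Molecular diffusion coefficient of radon in air
#'   (m^2 s^-1).
#' @return Object of class `source_spec`.
#' @export
source_spec <- function(exhalation = 3.1, c_out = 10,
                        decay_constant = 2.1e-6, diffusion = 1.2e-5) {
  walls <- c("x0", "x1", "y0", "y1", "z0", "z1")
  if (length(exhalation) == 1 && is.null(names(exhalation))) {
    exhalation <- stats::setNames(rep(as.numeric(exhalation), 6), walls)
  } else {
    e <- stats::setNames(rep(0, 6), walls)
    e[names(exhalation)] <- as.numeric(exhalation)
    exhalation <- e
  }
  if (any(exhalation < 0) || c_out < 0 || decay_constant < 0 || diffusion < 0) {
    stop("source_spec: all rates and constants must be non-negative")
  }
  structure(list(exhalation = exhalation, c_out = c_out,
                 decay_constant = decay_constant, diffusion = diffusion),
            class = "source_spec")
}

#' Volumetric radon generation rate from surface exhalation
#'
#' `G = sum(E_i * A_i) / V`: total exhalation over the room surfaces
#' divided by the room volume.
#'
#' @param E Exhalation rate(s), Bq m^-2 h^-1 (recycled over `A`).
#' @param A Surface areas, m^2.
#' @param V Room volume, m^3.
#' @return List with `per_hour` (Bq m^-3 h^-1) and `per_second`
#'   (Bq m^-3 s^-1).
#' @export
volumetric_generation_rate <- function(E, A, V) {
  if (V <= 0) stop("volumetric_generation_rate: V must be positive")
  g <- sum(E * A) / V
  list(per_hour = g, per_second = g / 3600)
}

# surface areas of the six walls of a room box, named by wall id
wall_areas <- function(geom) {
  c(x0 = geom$Ly * geom$Lz, x1 = geom$Ly * geom$Lz,
    y0 = geom$Lx * geom$Lz, y1 = geom$Lx * geom$Lz,
    z0 = geom$Lx * geom$Ly, z1 = geom$Lx * geom$Ly)
}

# ---------------------------------------------------------------------------
# Generic conservative finite-volume assembly of the steady
# advection-diffusion-decay equation on the structured grid, first-order
# upwind advection (positivity-preserving M-matrix).  All equations are
# volume-integrated with time in seconds.
#
# bc: list per wall, each list(type, value) where type is one of
# "zero_flux", "advective_in", "outflow", "flux", "dirichlet" and value a
# scalar or a matrix over the wall's faces.  "flux" values are in
# concentration * m s^-1 (i.e. Bq m^-2 s^-1 for radon), positive into the
# domain.
assemble_scalar_system <- function(grid, u, v, w, gamma, lambda, source, bc) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  Ax <- grid$dy * grid$dz; Ay <- grid$dx * grid$dz; Az <- grid$dx * grid$dy
  vol <- grid$cell_volume
  N <- nx * ny * nz
  id <- array(seq_len(N), dim = c(nx, ny, nz))
  diag_ <- numeric(N)
  rhs <- as.numeric(source) * vol
  ti <- list(); tj <- list(); tx <- list(); nt <- 0
  push <- function(i, j, x) {
    nt <<- nt + 1
    ti[[nt]] <<- as.integer(i); tj[[nt]] <<- as.integer(j); tx[[nt]] <<- x
  }

  internal <- function(P, E, q, gP, gE, D0) {
    Dc <- 0.5 * (gP + gE) * D0
    app <- pmax(q, 0) + Dc   # P's diagonal gain, E couples via -ape
    ape <- pmax(-q, 0) + Dc
    push(P, E, -ape)
    push(E, P, -app)
    diag_[P] <<- diag_[P] + app
    diag_[E] <<- diag_[E] + ape
  }

  if (nx > 1) {
    P <- id[1:(nx - 1), , ]; E <- id[2:nx, , ]
    q <- u[2:nx, , , drop = FALSE] * Ax
    internal(P, E, q, gamma[1:(nx - 1), , ], gamma[2:nx, , ], Ax / grid$dx)
  }
  if (ny > 1) {
    P <- id[, 1:(ny - 1), ]; E <- id[, 2:ny, ]
    q <- v[, 2:ny, , drop = FALSE] * Ay
    internal(P, E, q, gamma[, 1:(ny - 1), ], gamma[, 2:ny, ], Ay / grid$dy)
  }
  if (nz > 1) {
    P <- id[, , 1:(nz - 1)]; E <- id[, , 2:nz]
    q <- w[, , 2:nz, drop = FALSE] * Az
    internal(P, E, q, gamma[, , 1:(nz - 1)], gamma[, , 2:nz], Az / grid$dz)
  }

  boundary <- function(P, qo, gP, area, halfdist, spec) {
    # qo: outward-positive volumetric flux per face (m^3 s^-1)
    type <- spec$type
    val <- spec$value
    if (length(val) == 1) val <- rep(val, length(P))
    if (length(type) == 1) type <- rep(type, length(P))
    adv_out <- pmax(qo, 0); adv_in <- pmax(-qo, 0)
    for (tp in unique(type)) {
      sel <- which(type == tp)
      if (tp == "zero_flux") next
      if (tp == "flux") {
        rhs[P[sel]] <<- rhs[P[sel]] + val[sel] * area
      } else if (tp == "advective_in") {
        diag_[P[sel]] <<- diag_[P[sel]] + adv_out[sel]
        rhs[P[sel]] <<- rhs[P[sel]] + adv_in[sel] * val[sel]
      } else if (tp == "outflow") {
        diag_[P[sel]] <<- diag_[P[sel]] + adv_out[sel]
      } else if (tp == "dirichlet") {
        Db <- gP[sel] * area / halfdist
        diag_[P[sel]] <<- diag_[P[sel]] + Db + adv_out[sel]
        rhs[P[sel]] <<- rhs[P[sel]] + (Db + adv_in[sel]) * val[sel]
      } else stop("unknown boundary type: ", tp)
    }
  }

  boundary(c(id[1, , ]), c(-u[1, , ] * Ax), c(gamma[1, , ]), Ax, grid$dx / 2, bc$x0)
  boundary(c(id[nx, , ]), c(u[nx + 1, , ] * Ax), c(gamma[nx, , ]), Ax, grid$dx / 2, bc$x1)
  boundary(c(id[, 1, ]), c(-v[, 1, ] * Ay), c(gamma[, 1, ]), Ay, grid$dy / 2, bc$y0)
  boundary(c(id[, ny, ]), c(v[, ny + 1, ] * Ay), c(gamma[, ny, ]), Ay, grid$dy / 2, bc$y1)
  boundary(c(id[, , 1]), c(-w[, , 1] * Az), c(gamma[, , 1]), Az, grid$dz / 2, bc$z0)
  boundary(c(id[, , nz]), c(w[, , nz + 1] * Az), c(gamma[, , nz]), Az, grid$dz / 2, bc$z1)

  diag_ <- diag_ + lambda * vol
  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(N, N)) + Matrix::Diagonal(N, diag_)
  list(A = A, b = rhs)
}

# map grid boundary tags + source spec to scalar boundary conditions
radon_bc_from_tags <- function(grid, src, source_mode) {
  lapply(stats::setNames(names(grid$tags), names(grid$tags)), function(wl) {
    tg <- c(grid$tags[[wl]])
    type <- rep("zero_flux", length(tg))
    value <- rep(0, length(tg))
    type[tg == TAG_INLET] <- "advective_in"
    value[tg == TAG_INLET] <- src$c_out
    type[tg == TAG_OUTLET] <- "outflow"
    if (source_mode == "boundary_flux") {
      wallsel <- tg == TAG_WALL | tg == TAG_LID
      type[wallsel] <- "flux"
      value[wallsel] <- src$exhalation[[wl]] / 3600
    }
    list(type = type, value = value)
  })
}

#' Solve steady radon transport on a frozen flow field
#'
#' Finite-volume discretization of the steady advection-diffusion-decay
#' equation for the radon activity concentration, with first-order upwind
#' advection (positivity-preserving), effective diffusivity
#' `D + nu_t / Sc_t`, inlet advected concentration `c_out`, advective
#' outflow at the pressure outlets, and either prescribed exhalation flux
#' on the walls (`boundary_flux`) or a uniform volumetric generation rate
#' (`volumetric`). The linear system is solved directly (sparse LU).
#'
#' @param grid A `room_grid`.
#' @param flow A converged `flow_field` on the same grid.
#' @param src A [source_spec()].
#' @param source_mode `"boundary_flux"` (physical default) or
#'   `"volumetric"`.
#' @param G Volumetric generation rate (Bq m^-3 h^-1) for the
#'   `volumetric` mode; defaults to `sum(E_i A_i) / V` from `src` and the
#'   room geometry.
#' @param sc_t Turbulent Schmidt number for the effective diffusivity.
#' @return Object of class `radon_field` with the cell `concentration`
#'   array (Bq m^-3) and its `volume_average`.
#' @export
solve_radon <- function(grid, flow, src = source_spec(),
                        source_mode = c("boundary_flux", "volumetric"),
                        G = NULL, sc_t = 0.7) {
  source_mode <- match.arg(source_mode)
  stopifnot(inherits(grid, "room_grid"))
  rho <- flow$air$density %||% 1
  gamma <- src$diffusion + flow$mut / (rho * sc_t)
  if (length(gamma) == 1) gamma <- array(gamma, dim = c(grid$nx, grid$ny, grid$nz))
  lambda <- src$decay_constant
  source <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  if (source_mode == "volumetric") {
    if (is.null(G)) {
      if (is.null(grid$geom)) stop("solve_radon: G required for a bare grid")
      G <- volumetric_generation_rate(src$exhalation, wall_areas(grid$geom),
                                      grid$geom$volume)$per_hour
    }
    source[] <- G / 3600
  }
  bc <- radon_bc_from_tags(grid, src, source_mode)
  sys <- assemble_scalar_system(grid, flow$u, flow$v, flow$w, gamma, lambda,
                                source, bc)
  conc <- as.numeric(Matrix::solve(sys$A, sys$b))
  if (any(conc < -1e-8 * max(abs(conc)))) {
    stop("solve_radon: negative concentrations; discretization error")
  }
  conc <- pmax(conc, 0)
  field <- structure(list(
    concentration = array(conc, dim = c(grid$nx, grid$ny, grid$nz)),
    volume_average = mean(conc),
    source_mode = source_mode, G = G, src = src, sc_t = sc_t),
    class = "radon_field")
  field
}

#' @export
print.radon_field <- function(x, ...) {
  cat(sprintf("radon field (%s source): volume average %.2f Bq/m^3, range %.2f..%.2f\n",
              x$source_mode, x$volume_average, min(x$concentration),
              max(x$concentration)))
  invisible(x)
}

#' Volume-weighted mean concentration
#'
#' @param field A `radon_field` (or bare concentration array).
#' @param grid The `room_grid`.
#' @return Bq m^-3.
#' @export
volume_average <- function(field, grid) {
  conc <- if (inherits(field, "radon_field")) field$concentration else field
  # uniform cells: the volume-weighted mean reduces to the plain mean
  sum(conc * grid$cell_volume) / (length(conc) * grid$cell_volume)
}

# pick the (x, y, z) coordinate columns of a matrix/data.frame, by name
# when present, by position otherwise
coordinate_matrix <- function(points) {
  df <- as.data.frame(points)
  if (all(c("x", "y", "z") %in% names(df))) {
    df <- df[, c("x", "y", "z")]
  } else {
    df <- df[, 1:3]
  }
  m <- data.matrix(df)
  if (!is.numeric(m)) stop("points must be numeric (x, y, z) coordinates")
  m
}

#' Sample a cell field at physical points by trilinear interpolation
#'
#' Interpolates between cell centres; points in the half-cell next to a
#' boundary are clamped to the nearest cell-centre plane.
#'
#' @param field A `radon_field` or a 3-d cell array.
#' @param grid The `room_grid`.
#' @param points Numeric matrix (n x 3) or data.frame with columns x, y, z
#'   in metres.
#' @return Numeric vector of sampled values.
#' @export
sample_at <- function(field, grid, points) {
  conc <- if (inherits(field, "radon_field")) field$concentration else field
  pts <- coordinate_matrix(points)
  L <- c(grid$Lx, grid$Ly, grid$Lz)
  out_of_room <- pts[, 1] < 0 | pts[, 1] > L[1] |
    pts[, 2] < 0 | pts[, 2] > L[2] | pts[, 3] < 0 | pts[, 3] > L[3]
  if (any(out_of_room)) {
    bad <- which(out_of_room)[1]
    stop(sprintf("sample_at: point (%g, %g, %g) lies outside the room",
                 pts[bad, 1], pts[bad, 2], pts[bad, 3]))
  }
  d <- c(grid$dx, grid$dy, grid$dz)
  n <- c(grid$nx, grid$ny, grid$nz)
  vapply(seq_len(nrow(pts)), function(r) {
    s <- pts[r, ] / d - 0.5          # fractional cell-centre coordinate
    s <- pmin(pmax(s, 0), n - 1)     # clamp boundary half-cells
    i0 <- pmin(floor(s), n - 2); i0 <- pmax(i0, 0)
    f <- s - i0
    acc <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      wgt <- (if (cx == 1) f[1] else 1 - f[1]) *
             (if (cy == 1) f[2] else 1 - f[2]) *
             (if (cz == 1) f[3] else 1 - f[3])
      acc <- acc + wgt * conc[i0[1] + 1 + cx, i0[2] + 1 + cy, i0[3] + 1 + cz]
    }
    acc
  }, numeric(1))
}

#' Steady activity balance of a radon solution
#'
#' Recomputes boundary and volumetric activity flows from the converged
#' field: exhalation + volumetric generation + inlet advection versus
#' outlet advection + decay.
#'
#' @param field A `radon_field` from [solve_radon()].
#' @param grid,flow The grid and flow field used.
#' @return List with the individual terms (Bq s^-1) and the `relative`
#'   residual (imbalance over total input).
#' @export
radon_balance <- function(field, grid, flow) {
  src <- field$src
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  Ax <- grid$dy * grid$dz; Ay <- grid$dx * grid$dz; Az <- grid$dx * grid$dy
  conc <- field$concentration
  input_exhal <- 0; input_inlet <- 0; out_adv <- 0
  walls <- list(
    list(w = "x0", P = conc[1, , ], qo = -flow$u[1, , ] * Ax, A = Ax),
    list(w = "x1", P = conc[nx, , ], qo = flow$u[nx + 1, , ] * Ax, A = Ax),
    list(w = "y0", P = conc[, 1, ], qo = -flow$v[, 1, ] * Ay, A = Ay),
    list(w = "y1", P = conc[, ny, ], qo = flow$v[, ny + 1, ] * Ay, A = Ay),
    list(w = "z0", P = conc[, , 1], qo = -flow$w[, , 1] * Az, A = Az),
    list(w = "z1", P = conc[, , nz], qo = flow$w[, , nz + 1] * Az, A = Az))
  for (bl in walls) {
    tg <- grid$tags[[bl$w]]
    if (field$source_mode == "boundary_flux") {
      nwall <- sum(tg == TAG_WALL | tg == TAG_LID)
      input_exhal <- input_exhal + nwall * bl$A * src$exhalation[[bl$w]] / 3600
    }
    sel_in <- tg == TAG_INLET
    input_inlet <- input_inlet + sum(pmax(-bl$qo[sel_in], 0) * src$c_out)
    sel_out <- tg == TAG_OUTLET
    out_adv <- out_adv + sum(pmax(bl$qo[sel_out], 0) * bl$P[sel_out])
  }
  input_vol <- if (field$source_mode == "volumetric") {
    field$G / 3600 * grid$cell_volume * length(conc)
  } else 0
  decay <- src$decay_constant * sum(conc) * grid$cell_volume
  input <- input_exhal + input_inlet + input_vol
  list(exhalation = input_exhal, inlet = input_inlet, volumetric = input_vol,
       outlet = out_adv, decay = decay,
       relative = (input - out_adv - decay) / max(input, 1e-300))
}
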