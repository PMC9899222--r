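#' Write cell fields to a legacy ASCII VTK structured-points file
#'
#' Fields are written as point data located at the cell centres, suitable
#' for ParaView/VisIt inspection.
#'
#' @param grid A `room_grid`.
#' @param fields Named list of 3-d cell arrays (scalars) and/or a list
#'   entry `velocity` of three cell-centred component arrays.
#' @param path Output `.vtk` path.
#' @return The path, invisibly.
#' @export
write_vtk <- function(grid, fields, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "radonroom field export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$nx, grid$ny, grid$nz),
               sprintf("ORIGIN %g %g %g", grid$dx / 2, grid$dy / 2, grid$dz / 2),
               sprintf("SPACING %g %g %g", grid$dx, grid$dy, grid$dz),
               sprintf("POINT_DATA %d", grid$nx * grid$ny * grid$nz)), con)
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.list(f)) {
      writeLines(sprintf("VECTORS %s double", nm), con)
      m <- cbind(as.numeric(f[[1]]), as.numeric(f[[2]]), as.numeric(f[[3]]))
      utils::write.table(format(m, digits = 9, trim = TRUE), con,
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(as.numeric(f), digits = 9, trim = TRUE), con)
    }
  }
  invisible(path)
}

# cell-centred velocity components from a staggered flow field
cell_velocity <- function(field, grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  list(
    0.5 * (field$u[1:nx, , , drop = FALSE] + field$u[2:(nx + 1), , , drop = FALSE]),
    0.5 * (field$v[, 1:ny, , drop = FALSE] + field$v[, 2:(ny + 1), , drop = FALSE]),
    0.5 * (field$w[, , 1:nz, drop = FALSE] + field$w[, , 2:(nz + 1), drop = FALSE]))
}

solver_settings_from_config <- function(config) {
  sv <- config$solver
  solver_settings(
    closure = sv$closure %||% "constant_nu_eff",
    tolerance = sv$tolerance %||% 1e-6,
    max_iterations = sv$max_iterations %||% 5000,
    relax_momentum = sv$relax_momentum %||% 0.7,
    relax_pressure = sv$relax_pressure %||% 0.3,
    relax_turbulence = sv$relax_turbulence %||% 0.5,
    advection = sv$advection %||% "hybrid",
    nu_eff = sv$nu_eff)
}

#' Run the full pipeline: configure, flow, radon, box model, dose
#'
#' Executes the stages in order on one scenario, writes VTK fields, CSV
#' tables (volume average vs the analytical value, point samples at the
#' detector grid, dose summary) and a JSON run manifest. Deterministic:
#' re-running an identical configuration reproduces identical outputs.
#'
#' @param config `NULL`, a named list, or a YAML config path (see
#'   [build_room()] for the schema).
#' @param outdir Output directory (created if needed).
#' @return The run manifest (named list), invisibly the same as the JSON
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("radonroom_run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  validate_config(config)
  geom <- build_room(config)
  grid <- generate_grid(geom, config$grid$resolution %||%
                          (if (!is.null(config$grid$nx))
                             c(config$grid$nx, config$grid$ny, config$grid$nz)
                           else 10))
  ach <- config$ventilation$ach %||% 1
  vent <- ventilation_spec(ach, geom)
  aircfg <- config$air
  air <- air_properties(aircfg$temperature %||% 24, aircfg$rh %||% 0.5,
                        aircfg$pressure %||% 101325)
  settings <- solver_settings_from_config(config)
  srccfg <- config$source
  src <- source_spec(exhalation = srccfg$exhalation %||% 3.1,
                     c_out = srccfg$c_out %||% 10,
                     decay_constant = srccfg$decay_constant %||% 2.1e-6,
                     diffusion = srccfg$diffusion %||% 1.2e-5)
  mode <- srccfg$mode %||% "boundary_flux"
  if (!mode %in% c("boundary_flux", "volumetric")) {
    stop("config source.mode must be 'boundary_flux' or 'volumetric'")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  flow <- solve_flow(grid, vent, air, settings)
  radon <- solve_radon(grid, flow, src, source_mode = mode, G = srccfg$g)

  # outputs
  files <- character(0)
  vtk_flow <- file.path(outdir, "flow.vtk")
  write_vtk(grid, list(velocity = cell_velocity(flow, grid),
                       pressure = flow$pressure, k = flow$k,
                       epsilon = flow$epsilon, mut = flow$mut), vtk_flow)
  vtk_radon <- file.path(outdir, "radon.vtk")
  write_vtk(grid, list(concentration = radon$concentration), vtk_radon)
  files <- c(files, vtk_flow, vtk_radon)

  pts <- detector_points()
  probes <- cbind(pts, concentration = sample_at(radon, grid, pts[, c("x", "y", "z")]))
  probes_csv <- file.path(outdir, "probes.csv")
  utils::write.csv(probes, probes_csv, row.names = FALSE)
  files <- c(files, probes_csv)

  g_eff <- radon$G %||% volumetric_generation_rate(src$exhalation,
                                                   wall_areas(geom),
                                                   geom$volume)$per_hour
  wm <- wellmixed_params(G = g_eff, ach = ach, c_out = src$c_out,
                         lambda_rn = src$decay_constant * 3600)
  tab2 <- build_table2(ach, stats::setNames(list(radon$volume_average),
                                            geom$scenario), wm)
  tab2_csv <- file.path(outdir, "table_ach.csv")
  utils::write.csv(tab2$table, tab2_csv, row.names = FALSE)
  files <- c(files, tab2_csv)

  dp <- dose_params()
  doses <- data.frame(
    quantity = c("volume_average", paste0("point_", probes$point, "_z",
                                          probes$z * 100, "cm")),
    concentration_bq_m3 = c(radon$volume_average, probes$concentration))
  doses$aed_msv_yr <- annual_effective_dose(doses$concentration_bq_m3, dp)
  doses_csv <- file.path(outdir, "doses.csv")
  utils::write.csv(doses, doses_csv, row.names = FALSE)
  files <- c(files, doses_csv)

  manifest <- list(
    package_version = as.character(utils::packageVersion("radonroom")),
    scenario = geom$scenario, ach = ach,
    grid = c(grid$nx, grid$ny, grid$nz),
    closure = settings$closure, advection = settings$advection,
    tolerance = settings$tolerance,
    source_mode = mode, generation_rate_bq_m3_h = g_eff,
    flow_iterations = flow$iterations, flow_converged = flow$converged,
    volume_average_bq_m3 = radon$volume_average,
    analytical_bq_m3 = wellmixed_steady(wm),
    outputs = basename(files),
    checksums = stats::setNames(
      vapply(files, function(f) unname(tools::md5sum(f)), character(1)),
      basename(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Ventilation-rate sweep
#'
#' Solves flow and radon once per air-change rate on a shared grid and
#' writes the volume-average-versus-ACH table together with the
#' analytical values.
#'
#' @param config As in [run_pipeline()].
#' @param ach_list Positive air-change rates (h^-1).
#' @param outdir Output directory.
#' @param source_mode,G Passed to [solve_radon()].
#' @return Data frame with one row per ACH (also written to
#'   `ach_sweep.csv`), invisibly.
#' @export
run_ach_sweep <- function(config = NULL, ach_list,
                          outdir = tempfile("radonroom_sweep"),
                          source_mode = "volumetric", G = NULL) {
  if (length(ach_list) == 0) stop("run_ach_sweep: empty ach list")
  if (any(ach_list <= 0)) stop("run_ach_sweep: ach values must be positive")
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  validate_config(config)
  geom <- build_room(config)
  grid <- generate_grid(geom, config$grid$resolution %||% 10)
  aircfg <- config$air
  air <- air_properties(aircfg$temperature %||% 24, aircfg$rh %||% 0.5,
                        aircfg$pressure %||% 101325)
  settings <- solver_settings_from_config(config)
  srccfg <- config$source
  src <- source_spec(exhalation = srccfg$exhalation %||% 3.1,
                     c_out = srccfg$c_out %||% 10,
                     decay_constant = srccfg$decay_constant %||% 2.1e-6,
                     diffusion = srccfg$diffusion %||% 1.2e-5)
  G <- G %||% srccfg$g
  rows <- lapply(ach_list, function(a) {
    vent <- ventilation_spec(a, geom)
    flow <- solve_flow(grid, vent, air, settings)
    radon <- solve_radon(grid, flow, src, source_mode = source_mode, G = G)
    g_eff <- radon$G %||% volumetric_generation_rate(src$exhalation,
                                                     wall_areas(geom),
                                                     geom$volume)$per_hour
    wm <- wellmixed_params(G = g_eff, ach = a, c_out = src$c_out,
                           lambda_rn = src$decay_constant * 3600)
    data.frame(ach = a, volume_average = radon$volume_average,
               analytical = wellmixed_steady(wm),
               difference_pct = percentage_difference(wellmixed_steady(wm),
                                                      radon$volume_average))
  })
  out <- do.call(rbind, rows)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out, file.path(outdir, "ach_sweep.csv"), row.names = FALSE)
  invisible(out)
}
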