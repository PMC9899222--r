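# shared small configurations used across test files

small_room_run <- local({
  cache <- new.env(parent = emptyenv())
  function(scenario = "closed", resolution = 4, ach = 1,
           closure = "constant_nu_eff") {
    key <- paste(scenario, resolution, ach, closure, sep = "_")
    if (is.null(cache[[key]])) {
      geom <- room_geometry(scenario = scenario)
      grid <- generate_grid(geom, resolution)
      air <- air_properties()
      flow <- solve_flow(grid, ventilation_spec(ach, geom), air,
                         solver_settings(closure = closure,
                                         max_iterations = 6000))
      cache[[key]] <- list(geom = geom, grid = grid, air = air, flow = flow)
    }
    cache[[key]]
  }
})

# effective generation rate calibrated from the published analytical value
# at ACH = 0.3 (fixture table), used wherever the volumetric source mode
# needs the table-consistent G
calibrated_G <- function() {
  tab <- utils::read.csv(system.file("extdata", "ach_table.csv",
                                     package = "radonroom"))
  calibrate_generation(tab$analytical[tab$ach == 0.3], ach = 0.3,
                       c_out = 10, lambda_rn = 2.1e-6 * 3600)
}
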