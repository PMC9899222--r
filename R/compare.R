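#' Signed percentage difference between analytical and numerical values
#'
#' `(analytical - numerical) / analytical * 100`, the convention used when
#' benchmarking simulated volume averages against the box model.
#'
#' @param analytical Analytical (reference) value(s), > 0.
#' @param numerical Numerical value(s).
#' @return Percentage difference(s).
#' @export
percentage_difference <- function(analytical, numerical) {
  if (any(analytical <= 0)) {
    stop("percentage_difference: analytical values must be positive")
  }
  (analytical - numerical) / analytical * 100
}

#' Absolute relative deviation of a measurement from a prediction
#'
#' `|measured - predicted| / predicted * 100`, the detector-validation
#' metric.
#'
#' @param measured Measured value(s).
#' @param predicted Predicted (simulated) value(s), > 0.
#' @return Relative deviation(s) in percent (always >= 0).
#' @export
relative_deviation <- function(measured, predicted) {
  if (any(predicted <= 0)) {
    stop("relative_deviation: predicted values must be positive")
  }
  abs(measured - predicted) / predicted * 100
}

#' A set of detector measurements at points in the room
#'
#' @param device Device label (`"AlphaGUARD"`, `"RAD7"`, `"Raduet"`,
#'   `"NRPB"` or `"synthetic"`).
#' @param records Data frame with columns `x`, `y`, `z` (m) and
#'   `concentration` (Bq m^-3); optional `point` labels.
#' @param scenario,ach Scenario ("open"/"closed") and ventilation rate the
#'   measurements refer to.
#' @param geom Optional [room_geometry()] used to validate coordinates.
#' @return Object of class `measurement_set`.
#' @export
measurement_set <- function(device, records, scenario = NA, ach = NA,
                            geom = NULL) {
  stopifnot(all(c("x", "y", "z", "concentration") %in% names(records)))
  if (any(records$concentration < 0)) {
    stop("measurement_set: concentrations must be non-negative")
  }
  if (!is.null(geom)) {
    inside <- records$x >= 0 & records$x <= geom$Lx &
      records$y >= 0 & records$y <= geom$Ly &
      records$z >= 0 & records$z <= geom$Lz
    if (!all(inside)) stop("measurement_set: coordinates outside the room")
  }
  structure(list(device = device, records = as.data.frame(records),
                 scenario = scenario, ach = ach),
            class = "measurement_set")
}

#' Read measurement sets from a CSV file
#'
#' Expected columns: `device`, `scenario`, `ach`, `point` (optional),
#' `x_m`, `y_m`, `z_m`, `concentration_bq_m3`.
#'
#' @param path CSV file path.
#' @return A list of `measurement_set` objects, one per device.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("device", "x_m", "y_m", "z_m", "concentration_bq_m3")
  if (!all(need %in% names(df))) {
    stop("read_measurements: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  lapply(split(df, df$device), function(d) {
    rec <- data.frame(x = d$x_m, y = d$y_m, z = d$z_m,
                      concentration = d$concentration_bq_m3)
    if ("point" %in% names(d)) rec$point <- d$point
    measurement_set(d$device[1], rec,
                    scenario = if ("scenario" %in% names(d)) d$scenario[1] else NA,
                    ach = if ("ach" %in% names(d)) d$ach[1] else NA)
  })
}

#' Analytical-versus-numerical comparison table across ventilation rates
#'
#' For each air-change rate, evaluates the well-mixed steady concentration
#' (same generation rate, outdoor concentration and decay constant) and
#' the signed percentage difference against the supplied numerical volume
#' averages, mirroring the layout analytical / numerical / difference.
#'
#' @param ach_list Air-change rates, h^-1.
#' @param numerical Numeric vector (one scenario) or a data.frame/list
#'   with elements `open` and `closed` of numerical volume averages
#'   (Bq m^-3), aligned with `ach_list`.
#' @param params A [wellmixed_params()]; its `ach` entry is replaced by
#'   each value of `ach_list` in turn.
#' @return Object of class `comparison_report` wrapping a data.frame.
#' @export
build_table2 <- function(ach_list, numerical, params) {
  if (is.numeric(numerical)) numerical <- list(closed = numerical)
  lens <- vapply(numerical, length, integer(1))
  if (any(lens != length(ach_list))) {
    stop("build_table2: numerical values and ach_list lengths differ")
  }
  analytical <- vapply(ach_list, function(a) {
    p <- params; p$ach <- a
    wellmixed_steady(p)
  }, numeric(1))
  df <- data.frame(ach = ach_list, analytical = analytical)
  for (nm in names(numerical)) {
    df[[paste0("numerical_", nm)]] <- numerical[[nm]]
    df[[paste0("difference_pct_", nm)]] <-
      percentage_difference(analytical, numerical[[nm]])
  }
  structure(list(table = df, kind = "ach_sweep"), class = "comparison_report")
}

#' Detector-versus-prediction comparison
#'
#' Samples the simulated concentration field at the measurement
#' coordinates (trilinear interpolation) and reports per-point and
#' per-height-average relative deviations. Alternatively, explicit
#' `predictions` can be supplied instead of a field.
#'
#' @param field,grid A `radon_field` and its `room_grid` (ignored when
#'   `predictions` is given).
#' @param measurements A `measurement_set` or list of them.
#' @param predictions Optional numeric vector of predicted concentrations
#'   aligned with the measurement records.
#' @return Object of class `comparison_report`; its `table` has columns
#'   device, point, x, y, z, measured, predicted, relative_deviation_pct,
#'   and `summary` aggregates by device and height.
#' @export
build_detector_comparison <- function(field = NULL, grid = NULL,
                                      measurements, predictions = NULL) {
  if (inherits(measurements, "measurement_set")) {
    measurements <- list(measurements)
  }
  if (length(measurements) == 0 ||
      sum(vapply(measurements, function(m) nrow(m$records), integer(1))) == 0) {
    stop("build_detector_comparison: empty measurement set")
  }
  rows <- lapply(measurements, function(m) {
    rec <- m$records
    pred <- if (!is.null(predictions)) {
      predictions
    } else {
      if (is.null(field) || is.null(grid)) {
        stop("build_detector_comparison: need a field and grid, or predictions")
      }
      sample_at(field, grid, rec[, c("x", "y", "z")])
    }
    data.frame(device = m$device,
               point = if ("point" %in% names(rec)) rec$point else NA,
               x = rec$x, y = rec$y, z = rec$z,
               measured = rec$concentration, predicted = pred,
               relative_deviation_pct = relative_deviation(rec$concentration,
                                                           pred))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  summary <- do.call(rbind, lapply(split(tab, list(tab$device, tab$z),
                                         drop = TRUE), function(d) {
    data.frame(device = d$device[1], z = d$z[1],
               mean_measured = mean(d$measured),
               mean_predicted = mean(d$predicted),
               mean_relative_deviation_pct = mean(d$relative_deviation_pct),
               deviation_of_means_pct = relative_deviation(mean(d$measured),
                                                           mean(d$predicted)))
  }))
  rownames(summary) <- NULL
  structure(list(table = tab, summary = summary,
                 max_deviation_pct = max(tab$relative_deviation_pct),
                 kind = "detector"),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison report (", x$kind, ")\n", sep = "")
  print(x$table, digits = 4)
  if (!is.null(x$summary)) {
    cat("\nper-device / per-height summary:\n")
    print(x$summary, digits = 4)
    cat(sprintf("\nmaximum relative deviation: %.1f%%\n", x$max_deviation_pct))
  }
  invisible(x)
}

#' Write a comparison report to CSV
#'
#' @param report A `comparison_report`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
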