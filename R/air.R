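#' Inlet velocity from the air-change rate
#'
#' Converts an air-change rate (ACH) into the uniform inlet speed through
#' the ventilation opening: `V = ACH * V_room / A_vent`, expressed in SI
#' units (m s^-1, i.e. the natural m h^-1 divided by 3600).
#'
#' @param ach Air changes per hour (h^-1), >= 0.
#' @param room_volume Room volume (m^3).
#' @param vent_area Ventilation (window) area (m^2), > 0.
#' @return Inlet speed in m s^-1.
#' @export
inlet_velocity <- function(ach, room_volume, vent_area) {
  if (any(vent_area <= 0)) stop("inlet_velocity: vent_area must be positive")
  if (any(ach < 0)) stop("inlet_velocity: ach must be non-negative")
  ach * room_volume / (vent_area * 3600)
}

#' Ventilation specification for a room
#'
#' @param ach Air changes per hour (h^-1).
#' @param geom A [room_geometry()] (supplies volume and window area), or
#'   `NULL` if `room_volume` and `vent_area` are given directly.
#' @param room_volume,vent_area Overrides for the geometric values.
#' @return Object of class `ventilation_spec` with the derived inlet speed.
#' @export
ventilation_spec <- function(ach, geom = NULL, room_volume = NULL,
                             vent_area = NULL) {
  if (!is.null(geom)) {
    room_volume <- room_volume %||% geom$volume
    vent_area <- vent_area %||% geom$window$area
  }
  structure(list(ach = ach, room_volume = room_volume, vent_area = vent_area,
                 inlet_speed = inlet_velocity(ach, room_volume, vent_area)),
            class = "ventilation_spec")
}

# dry air and water vapour specific gas constants, J kg^-1 K^-1
R_DRY <- 287.058
R_VAP <- 461.495

# Magnus-type saturation vapour pressure over water, T in degC, result Pa.
saturation_vapour_pressure <- function(temperature) {
  611.2 * exp(17.62 * temperature / (243.12 + temperature))
}

#' Humid-air properties
#'
#' Density from the ideal-gas mixture of dry air and water vapour with a
#' Magnus-type saturation-pressure correlation; dynamic viscosity from
#' Sutherland's law for dry air (the humidity effect on viscosity is below
#' a percent at room temperature and is neglected).
#'
#' @param temperature Air temperature in degrees Celsius (-20..60).
#' @param rh Relative humidity as a fraction in `[0, 1]`.
#' @param pressure Total pressure (Pa); default one standard atmosphere.
#' @return Object of class `air_properties` with `density` (kg m^-3) and
#'   `dynamic_viscosity` (Pa s).
#' @export
air_properties <- function(temperature = 24, rh = 0.5, pressure = 101325) {
  if (rh < 0 || rh > 1) stop("air_properties: rh must lie in [0, 1]")
  if (temperature < -20 || temperature > 60) {
    stop("air_properties: temperature outside the supported -20..60 degC range")
  }
  tk <- temperature + 273.15
  p_v <- rh * saturation_vapour_pressure(temperature)
  p_d <- pressure - p_v
  density <- p_d / (R_DRY * tk) + p_v / (R_VAP * tk)
  # Sutherland's law, reference 1.716e-5 Pa s at 273.15 K, S = 110.4 K
  mu <- 1.716e-5 * (tk / 273.15)^1.5 * (273.15 + 110.4) / (tk + 110.4)
  structure(list(temperature = temperature, relative_humidity = rh,
                 pressure = pressure, density = density,
                 dynamic_viscosity = mu),
            class = "air_properties")
}

#' Reynolds number
#'
#' @param speed Flow speed (m s^-1).
#' @param length_scale Characteristic length (m), e.g. the hydraulic
#'   diameter of the window.
#' @param air An [air_properties()] object.
#' @return Dimensionless Reynolds number `rho * U * L / mu`.
#' @export
reynolds_number <- function(speed, length_scale, air = air_properties()) {
  air$density * speed * length_scale / air$dynamic_viscosity
}

#' Hydraulic diameter of a rectangular patch
#'
#' @param patch A [rect_patch()].
#' @return `4 A / P` in metres.
#' @export
hydraulic_diameter <- function(patch) {
  4 * patch$area / (2 * (patch$width + patch$height))
}
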