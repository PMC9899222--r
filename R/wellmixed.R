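#' Parameters of the analytical well-mixed (box) model
#'
#' Lumped single-zone mass balance for the indoor radon concentration:
#' `dC/dt = G + lambda_v (C_out - C) - lambda_rn C` (with outdoor inflow,
#' the default), or the literal source-plus-total-removal form
#' `dC/dt = G - (lambda_rn + lambda_v) C` when
#' `include_outdoor_inflow = FALSE`.
#'
#' @param G Volumetric generation rate, Bq m^-3 h^-1. Either `G` directly
#'   or `E`, `A`, `V` to derive it as `sum(E A) / V`.
#' @param ach Ventilation rate lambda_v, h^-1.
#' @param c_out Outdoor radon concentration, Bq m^-3.
#' @param lambda_rn Radon decay constant in h^-1 (default
#'   2.1e-6 s^-1 * 3600 = 7.56e-3 h^-1).
#' @param c0 Initial indoor concentration, Bq m^-3.
#' @param include_outdoor_inflow Include the ventilation supply term
#'   `lambda_v * C_out` (default `TRUE`).
#' @param E,A,V Optional exhalation rates (Bq m^-2 h^-1), areas (m^2) and
#'   volume (m^3) used when `G` is missing.
#' @return Object of class `wellmixed_params`.
#' @export
wellmixed_params <- function(G = NULL, ach, c_out = 10,
                             lambda_rn = 2.1e-6 * 3600, c0 = c_out,
                             include_outdoor_inflow = TRUE,
                             E = NULL, A = NULL, V = NULL) {
  if (is.null(G)) {
    if (is.null(E) || is.null(A) || is.null(V)) {
      stop("wellmixed_params: supply G, or E, A and V")
    }
    G <- volumetric_generation_rate(E, A, V)$per_hour
  }
  if (ach < 0 || lambda_rn < 0 || (ach + lambda_rn) <= 0) {
    stop("wellmixed_params: total removal rate lambda_rn + lambda_v must be positive")
  }
  if (G < 0 || c_out < 0 || c0 < 0) {
    stop("wellmixed_params: concentrations and G must be non-negative")
  }
  structure(list(G = G, ach = ach, c_out = c_out, lambda_rn = lambda_rn,
                 c0 = c0, include_outdoor_inflow = include_outdoor_inflow),
            class = "wellmixed_params")
}

#' Steady-state concentration of the well-mixed model
#'
#' With outdoor inflow: `(G + lambda_v C_out) / (lambda_rn + lambda_v)`;
#' without: `G / (lambda_rn + lambda_v)`.
#'
#' @param p A [wellmixed_params()].
#' @return Steady concentration, Bq m^-3.
#' @export
wellmixed_steady <- function(p) {
  lam <- p$lambda_rn + p$ach
  sup <- if (p$include_outdoor_inflow) p$ach * p$c_out else 0
  (p$G + sup) / lam
}

#' Time series of the well-mixed model
#'
#' Exact closed-form solution
#' `C(t) = C0 exp(-lambda t) + C_ss (1 - exp(-lambda t))` with
#' `lambda = lambda_rn + lambda_v` and `C_ss` the steady value.
#'
#' @param p A [wellmixed_params()].
#' @param times Times in hours, >= 0.
#' @return Concentrations at `times`, Bq m^-3.
#' @export
wellmixed_timeseries <- function(p, times) {
  if (any(times < 0)) stop("wellmixed_timeseries: times must be non-negative")
  lam <- p$lambda_rn + p$ach
  css <- wellmixed_steady(p)
  p$c0 * exp(-lam * times) + css * (1 - exp(-lam * times))
}

#' Calibrate the effective generation rate from an observed steady value
#'
#' Inverts the steady well-mixed balance (with outdoor inflow):
#' `G = C_ss (lambda_rn + lambda_v) - lambda_v C_out`.
#'
#' @param c_ss_observed Observed steady indoor concentration, Bq m^-3.
#' @param ach Ventilation rate, h^-1.
#' @param c_out Outdoor concentration, Bq m^-3.
#' @param lambda_rn Decay constant, h^-1.
#' @return Generation rate G, Bq m^-3 h^-1.
#' @export
calibrate_generation <- function(c_ss_observed, ach, c_out = 10,
                                 lambda_rn = 2.1e-6 * 3600) {
  lam <- lambda_rn + ach
  floor_c <- ach * c_out / lam
  if (c_ss_observed < floor_c - 1e-9) {
    stop(sprintf(paste0(
      "calibrate_generation: observed %.4g Bq/m^3 is below the outdoor-",
      "supported floor %.4g Bq/m^3 (ach*c_out/(ach+lambda_rn)); ",
      "no non-negative G reproduces it"), c_ss_observed, floor_c))
  }
  c_ss_observed * lam - ach * c_out
}

#' Dose-assessment parameters
#'
#' @param F Indoor radon equilibrium factor (UNSCEAR default 0.4).
#' @param occupancy Hours spent in the room per year (default 2000,
#'   workplace occupancy).
#' @param K Dose conversion factor, nSv per Bq h m^-3 (ICRP 115 value 12).
#' @return Object of class `dose_params`.
#' @export
dose_params <- function(F = 0.4, occupancy = 2000, K = 12) {
  if (!(F > 0 && F <= 1)) stop("dose_params: F must lie in (0, 1]")
  if (!(occupancy > 0 && occupancy <= 8760)) {
    stop("dose_params: occupancy must lie in (0, 8760] h/yr")
  }
  if (K <= 0) stop("dose_params: K must be positive")
  structure(list(F = F, occupancy = occupancy, K = K), class = "dose_params")
}

#' Annual effective dose from radon inhalation
#'
#' `AED = C * F * t * K`, converted from nSv to mSv.
#'
#' @param C Radon concentration(s), Bq m^-3.
#' @param d A [dose_params()].
#' @return Annual effective dose, mSv yr^-1.
#' @export
annual_effective_dose <- function(C, d = dose_params()) {
  if (any(C < 0)) stop("annual_effective_dose: C must be non-negative")
  C * d$F * d$occupancy * d$K * 1e-6
}
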