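#' Pressure values with explicit units
#'
#' A thin numeric wrapper carrying a pressure unit, so that quantities such
#' as P_crit (atm) and pO2 fields (mbar) cannot be silently mixed.
#' Supported units: `"atm"`, `"kPa"`, `"mbar"`, related by the exact
#' definitions 1 atm = 101.325 kPa = 1013.25 mbar.
#'
#' @param x numeric vector or array of non-negative pressures.
#' @param unit one of `"atm"`, `"kPa"`, `"mbar"`.
#' @return an object of class `"pressure"` (numeric with a `unit` attribute).
#' @examples
#' p <- pressure_value(1, "atm")
#' convert_pressure(p, "kPa")   # 101.325 kPa
#' @export
pressure_value <- function(x, unit = c("atm", "kPa", "mbar")) {
  unit <- match.arg(unit)
  if (any(x < 0, na.rm = TRUE)) stop("pressure must be non-negative")
  structure(x, unit = unit, class = "pressure")
}

.mbar_per_unit <- c(atm = 1013.25, kPa = 10, mbar = 1)

# drop pressure bookkeeping, keep array shape
.strip_unit <- function(x) {
  d <- dim(x)
  x <- as.vector(unclass(x))
  dim(x) <- d
  x
}

#' Convert a pressure value between units
#'
#' @param p a `"pressure"` object (see [pressure_value()]).
#' @param unit target unit, one of `"atm"`, `"kPa"`, `"mbar"`.
#' @return a `"pressure"` object in the target unit.
#' @export
convert_pressure <- function(p, unit = c("atm", "kPa", "mbar")) {
  unit <- match.arg(unit)
  from <- attr(p, "unit")
  if (is.null(from) || !from %in% names(.mbar_per_unit))
    stop("'p' must be a pressure_value() with a known unit")
  out <- unclass(p) * .mbar_per_unit[[from]] / .mbar_per_unit[[unit]]
  pressure_value(out, unit)
}

#' @export
print.pressure <- function(x, ...) {
  cat(format(unclass(x)), attr(x, "unit"), "\n")
  invisible(x)
}

#' Oxygen solubility in seawater
#'
#' Equilibrium dissolved-oxygen concentration with respect to water-saturated
#' air at one atmosphere total pressure, from the Garcia and Gordon (1992)
#' combined fit to the Benson and Krause data, in umol/kg. Strictly
#' decreasing in both temperature and salinity over the fitted range.
#'
#' @param T temperature, degrees Celsius, in [-2, 40].
#' @param S practical salinity, PSU, in [0, 42].
#' @return O2 solubility, umol/kg (same shape as the inputs).
#' @references Garcia, H.E. and Gordon, L.I. (1992) Oxygen solubility in
#'   seawater: better fitting equations. Limnol. Oceanogr. 37, 1307-1312.
#' @examples
#' o2_saturation(10, 35)  # about 274.6 umol/kg
#' @export
o2_saturation <- function(T, S) {
  if (any(T < -2 | T > 40, na.rm = TRUE)) stop("T outside [-2, 40] degC")
  if (any(S < 0 | S > 42, na.rm = TRUE)) stop("S outside [0, 42] PSU")
  A <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  B <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  C0 <- -2.75915e-7
  Ts <- log((298.15 - T) / (273.15 + T))
  lnC <- A[1] + Ts * (A[2] + Ts * (A[3] + Ts * (A[4] + Ts * (A[5] + Ts * A[6])))) +
    S * (B[1] + Ts * (B[2] + Ts * (B[3] + Ts * B[4]))) + C0 * S^2
  exp(lnC)
}

#' Saturation water vapour pressure over seawater
#'
#' Weiss and Price (1980) formulation; companion to the solubility fit used
#' in the dissolved O2 to pO2 conversion.
#'
#' @inheritParams o2_saturation
#' @return vapour pressure, mbar.
#' @export
vapour_pressure <- function(T, S) {
  TK <- T + 273.15
  .P_atm_mbar * exp(24.4543 - 67.4509 * (100 / TK) - 4.8489 * log(TK / 100) -
                      0.000544 * S)
}

#' Oxygen partial pressure from dissolved oxygen
#'
#' Converts a dissolved O2 concentration to partial pressure via the
#' saturation state: pO2 = (O2 / O2_sat(T, S)) * xO2 * (P_atm - p_H2O(T, S)),
#' with xO2 = 0.20946 and P_atm = 1013.25 mbar. Linear in O2 at fixed T, S;
#' 100 percent saturation maps to the moist-air O2 pressure.
#'
#' @param O2 dissolved oxygen, umol/kg (non-negative; any shape).
#' @param T temperature, degrees Celsius.
#' @param S salinity, PSU.
#' @return a `"pressure"` object in mbar, same shape as `O2`.
#' @examples
#' partial_pressure(100, 10, 35)
#' @export
partial_pressure <- function(O2, T, S) {
  if (any(O2 < 0, na.rm = TRUE)) stop("O2 must be non-negative")
  p <- (O2 / o2_saturation(T, S)) * .x_O2 * (.P_atm_mbar - vapour_pressure(T, S))
  pressure_value(p, "mbar")
}

# bare-numeric conversion used on large arrays (no class bookkeeping)
.po2_mbar <- function(O2, T, S) {
  (O2 / o2_saturation(T, S)) * .x_O2 * (.P_atm_mbar - vapour_pressure(T, S))
}
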