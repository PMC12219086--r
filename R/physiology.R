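#' Physiological trait sets for the metabolic index
#'
#' Bundles the traits entering the metabolic index and its critical oxygen
#' threshold: hypoxia tolerance A0 (1/atm, the inverse of P_crit at the
#' reference temperature), temperature sensitivity E0 (eV), reference
#' temperature T_ref (K), body mass B and allometric exponent n.
#'
#' Three archetype species spanning the spread of measured traits are
#' provided as presets: `"HHT"` (high hypoxia tolerance, A0 = 67/atm),
#' `"MHT"` (median, A0 = 23/atm) and `"LHT"` (low, A0 = 10/atm), all with
#' the median temperature sensitivity E0 = 0.34 eV. Their P_crit at T_ref
#' are approximately 1.5, 4.4 and 10.1 kPa.
#'
#' @param label preset name (`"HHT"`, `"MHT"`, `"LHT"`) or `"custom"`.
#' @param A0 hypoxia tolerance, 1/atm (> 0). Required when `label = "custom"`.
#' @param E0 temperature sensitivity, eV (sweeps are restricted to
#'   [-0.1, 0.9], the span of measured values).
#' @param T_ref reference temperature, K (default 288.15 K = 15 degC).
#' @param B body mass (default 1).
#' @param n allometric exponent (default 1).
#' @return an object of class `"physio_traits"`.
#' @examples
#' physio_traits("MHT")
#' physio_traits("custom", A0 = 30, E0 = 0.2)
#' @export
physio_traits <- function(label = c("MHT", "HHT", "LHT", "custom"),
                          A0 = NULL, E0 = 0.34, T_ref = 288.15,
                          B = 1, n = 1) {
  label <- match.arg(label)
  preset_A0 <- c(HHT = 67, MHT = 23, LHT = 10)
  if (label == "custom") {
    if (is.null(A0)) stop("A0 must be given for custom traits")
  } else {
    if (is.null(A0)) A0 <- preset_A0[[label]]
  }
  if (A0 <= 0) stop("A0 must be positive")
  if (E0 < -0.1 || E0 > 0.9)
    stop("E0 outside the supported range [-0.1, 0.9] eV")
  if (T_ref <= 0) stop("T_ref must be positive (Kelvin)")
  structure(list(A0 = A0, E0 = E0, T_ref = T_ref, B = B, n = n,
                 label = label),
            class = "physio_traits")
}

#' @export
print.physio_traits <- function(x, ...) {
  pc <- convert_pressure(pcrit(x, x$T_ref - 273.15), "kPa")
  cat(sprintf("physio_traits [%s]: A0 = %g /atm, E0 = %g eV, T_ref = %g K\n",
              x$label, x$A0, x$E0, x$T_ref))
  cat(sprintf("  P_crit at T_ref: %.3f kPa\n", unclass(pc)))
  invisible(x)
}

#' Critical oxygen partial pressure P_crit
#'
#' The temperature-dependent oxygen threshold at which supply equals the
#' standard metabolic demand (metabolic index equal to one):
#' P_crit = (1/A0) * exp(-E0/kB * (1/T - 1/T_ref)), with T in Kelvin.
#' At T = T_ref this reduces to 1/A0 for any E0; for E0 > 0 it increases
#' with temperature (warmer water demands more oxygen).
#'
#' @param traits a [physio_traits()] object.
#' @param T temperature, degrees Celsius (vector or array).
#' @return a `"pressure"` object in atm, same shape as `T`.
#' @examples
#' pcrit(physio_traits("MHT"), 15)              # 1/23 atm
#' convert_pressure(pcrit(physio_traits("MHT"), 15), "kPa")
#' @export
pcrit <- function(traits, T) {
  stopifnot(inherits(traits, "physio_traits"))
  pressure_value(.pcrit_atm(traits, T), "atm")
}

.pcrit_atm <- function(traits, T) {
  TK <- T + 273.15
  (1 / traits$A0) * exp(-traits$E0 / .kB_eV * (1 / TK - 1 / traits$T_ref))
}

#' Metabolic index
#'
#' Ratio of environmental oxygen supply to temperature-dependent oxygen
#' demand: Phi = A0 * pO2 * B^n * exp(E0/kB * (1/T - 1/T_ref)). Phi = 1
#' exactly when pO2 equals [pcrit()]; Phi > 1 marks metabolically suitable
#' conditions. Linear in pO2 at fixed temperature.
#'
#' @param traits a [physio_traits()] object.
#' @param pO2 oxygen partial pressure: a `"pressure"` object, or a bare
#'   numeric interpreted as atm.
#' @param T temperature, degrees Celsius.
#' @return dimensionless index, same shape as the inputs.
#' @examples
#' tr <- physio_traits("MHT")
#' metabolic_index(tr, pcrit(tr, 20), 20)  # 1 by construction
#' @export
metabolic_index <- function(traits, pO2, T) {
  stopifnot(inherits(traits, "physio_traits"))
  if (inherits(pO2, "pressure")) pO2 <- convert_pressure(pO2, "atm")
  pO2 <- .strip_unit(pO2)
  if (any(pO2 < 0, na.rm = TRUE)) stop("pO2 must be non-negative")
  TK <- T + 273.15
  traits$A0 * pO2 * traits$B^traits$n *
    exp(traits$E0 / .kB_eV * (1 / TK - 1 / traits$T_ref))
}
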