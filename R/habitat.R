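#' Metabolic suitability mask
#'
#' A cell is metabolically suitable when its oxygen partial pressure
#' strictly exceeds the temperature-dependent critical threshold:
#' pO2 > P_crit(T). Cells with missing pO2 or temperature (land) are
#' unsuitable. Equivalent to metabolic index > 1 cell-for-cell.
#'
#' @param pO2 oxygen partial pressure field, mbar by default (any shape).
#' @param T temperature field, degC, same shape.
#' @param traits a [physio_traits()] object.
#' @param po2_unit unit of `pO2` (`"mbar"`, `"atm"` or `"kPa"`).
#' @return logical array of the same shape; `TRUE` = suitable.
#' @export
suitability_mask <- function(pO2, T, traits, po2_unit = "mbar") {
  if (!identical(dim(pO2), dim(T)) && !(is.null(dim(pO2)) && is.null(dim(T))))
    stop("pO2 and T fields have different shapes")
  po2_atm <- unclass(pO2) * .mbar_per_unit[[po2_unit]] / .mbar_per_unit[["atm"]]
  m <- po2_atm > .pcrit_atm(traits, T)
  m[is.na(m)] <- FALSE
  m
}

#' Metabolically suitable habitat volume
#'
#' The aerobic habitat volume: the summed volume (km^3) of all grid cells
#' within the analysis domain whose pO2 strictly exceeds P_crit(T). Cells
#' are counted whole (no partial volumes at the crossing depth).
#' With `weight = "surplus"` an alternative diagnostic is returned instead:
#' the volume integral weighted by the pO2 surplus above P_crit (km^3 atm).
#'
#' @param pO2 `[depth, lat, lon]` partial-pressure field, mbar.
#' @param T `[depth, lat, lon]` temperature field, degC.
#' @param traits a [physio_traits()] object.
#' @param geom a [grid_geometry()] for the same grid.
#' @param domain optional list with `depth`, `lat`, `lon` ranges (cell
#'   centres are tested for membership); defaults to 0-600 m, 5-50 S,
#'   70-110 W.
#' @param weight `"cell"` (default: volume of suitable cells) or
#'   `"surplus"` (pO2-surplus-weighted integral).
#' @return volume, km^3 (or km^3 atm for `weight = "surplus"`).
#' @export
habitat_volume <- function(pO2, T, traits, geom, domain = NULL,
                           weight = c("cell", "surplus")) {
  weight <- match.arg(weight)
  stopifnot(inherits(geom, "grid_geometry"))
  if (!identical(dim(pO2), dim(geom$volume)))
    stop("field and grid geometry have different shapes")
  dm <- .domain_mask(geom, domain)
  if (!any(dm)) stop("empty analysis domain")
  mask <- suitability_mask(pO2, T, traits) & dm
  if (weight == "cell") {
    sum(geom$volume[mask])
  } else {
    surplus <- pO2 / .mbar_per_unit[["atm"]] - .pcrit_atm(traits, T)
    sum((surplus * geom$volume)[mask])
  }
}

# habitat volume of a state object (neutral_state or enso_state)
.state_volume <- function(state, traits, geom, domain = NULL, weight = "cell") {
  if (is.null(state$fields$pO2) || is.null(state$fields$T))
    stop("state must carry pO2 and T fields")
  habitat_volume(state$fields$pO2, state$fields$T, traits, geom, domain,
                 weight)
}

#' Habitat volume change between two states
#'
#' Signed difference of suitable habitat volume, `state2` minus `state1`
#' (positive = gain in `state2`); antisymmetric under swapping the states.
#'
#' @param state2,state1 states with `pO2` and `T` fields on the same grid
#'   ([reconstruct_enso_state()] / [neutral_climatology()] results).
#' @param traits a [physio_traits()] object.
#' @param geom a [grid_geometry()].
#' @param domain optional analysis domain (see [habitat_volume()]).
#' @return volume change, km^3.
#' @export
delta_volume <- function(state2, state1, traits, geom, domain = NULL) {
  if (!isTRUE(all.equal(state2$depth, state1$depth)) ||
      !isTRUE(all.equal(state2$lat, state1$lat)))
    stop("states are on different grids")
  .state_volume(state2, traits, geom, domain) -
    .state_volume(state1, traits, geom, domain)
}

#' Depth of the critical oxygen surface (Z_crit)
#'
#' The shallowest depth at which pO2 falls to P_crit(T) in a water column,
#' located by linear interpolation of pO2 - P_crit between the bracketing
#' levels. `NA` when the profile never crosses the threshold.
#'
#' @param pO2_profile pO2 at the column's depth levels, mbar.
#' @param T_profile temperature at the same levels, degC.
#' @param traits a [physio_traits()] object.
#' @param depth level depths, m, strictly increasing.
#' @return depth of the crossing, m, or `NA`.
#' @export
zcrit <- function(pO2_profile, T_profile, traits, depth) {
  if (length(depth) < 2) stop("profile needs at least 2 levels")
  g <- pO2_profile / .mbar_per_unit[["atm"]] - .pcrit_atm(traits, T_profile)
  s <- sign(g)
  flip <- which(s[-1] * s[-length(s)] < 0)
  exact <- which(g == 0)
  if (length(exact) && (!length(flip) || exact[1] <= flip[1]))
    return(depth[exact[1]])
  if (!length(flip)) return(NA_real_)
  i <- flip[1]
  depth[i] + (0 - g[i]) * (depth[i + 1] - depth[i]) / (g[i + 1] - g[i])
}

#' Z_crit over a gridded state
#'
#' @param state a state with `pO2` and `T` `[depth, lat, lon]` fields.
#' @param traits a [physio_traits()] object.
#' @return a `[lat, lon]` matrix of crossing depths (m; `NA` where the
#'   column never crosses).
#' @export
zcrit_field <- function(state, traits) {
  p <- state$fields$pO2; T <- state$fields$T
  d <- dim(p)
  out <- matrix(NA_real_, d[2], d[3])
  for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    out[j, k] <- zcrit(p[, j, k], T[, j, k], traits, state$depth)
  out
}

#' Per-event habitat states at the event peaks
#'
#' Reconstructs one ENSO state per detected event from its peak-season E
#' and C values.
#'
#' @param events an [detect_events()] / [subset_events()] result.
#' @param fit a [fit_teleconnection()] model.
#' @param neutral the [neutral_climatology()] reference state.
#' @return a list of `"enso_state"` objects, one per event.
#' @export
event_states <- function(events, fit, neutral) {
  stopifnot(inherits(events, "enso_events"))
  ev <- events$events
  lapply(seq_len(nrow(ev)), function(i)
    reconstruct_enso_state(neutral, fit, ev$peak_E[i], ev$peak_C[i]))
}

#' Probability of suitability flips across events
#'
#' For each cell, the percentage of events whose reconstructed state flips
#' the cell to suitable (gain) or to unsuitable (loss) relative to the
#' neutral state. Gain and loss percentages are mutually exclusive per
#' event and cell, so gain + loss <= 100 everywhere.
#'
#' @param states a list of `"enso_state"` objects (see [event_states()]),
#'   one per event.
#' @param neutral the [neutral_climatology()] reference state.
#' @param traits a [physio_traits()] object.
#' @return a list with `[depth, lat, lon]` arrays `gain_pct` and
#'   `loss_pct`, and `n_events`; `NULL` fields if `states` is empty.
#' @export
suitability_change_probability <- function(states, neutral, traits) {
  n <- length(states)
  if (n == 0)
    return(list(gain_pct = NULL, loss_pct = NULL, n_events = 0L))
  m0 <- suitability_mask(neutral$fields$pO2, neutral$fields$T, traits)
  gain <- loss <- array(0, dim(m0))
  for (s in states) {
    m <- suitability_mask(s$fields$pO2, s$fields$T, traits)
    gain <- gain + (m & !m0)
    loss <- loss + (!m & m0)
  }
  list(gain_pct = 100 * gain / n, loss_pct = 100 * loss / n, n_events = n)
}
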