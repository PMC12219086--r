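#' Lag composite of habitat-volume change across ENSO events
#'
#' For each lag relative to the event peaks, reconstructs the ENSO state
#' from the composite (event-averaged) E and C values at that lag and
#' computes the habitat-volume change against the neutral state
#' (`mode = "composite_state"`, the default). With `mode = "event_mean"`
#' the per-event volume changes are computed first and averaged.
#' Uncertainty is the bootstrap standard deviation across composites of
#' resampled event subsets (see [bootstrap_std()]), applied to the
#' per-event volume-change trajectories.
#'
#' @param events an [detect_events()] / [subset_events()] result (usually
#'   a single event type).
#' @param indices the [eof_ec_indices()] the events came from.
#' @param fit a [fit_teleconnection()] model (must include `pO2` and `T`).
#' @param neutral the [neutral_climatology()] reference state.
#' @param traits a [physio_traits()] object.
#' @param geom a [grid_geometry()].
#' @param lags month offsets relative to the January peak.
#' @param domain optional analysis domain.
#' @param mode composite definition, see Description.
#' @param n_boot,boot_frac,seed bootstrap settings (see [bootstrap_std()]).
#' @return an object of class `"composite_result"`: `lag`, `mean` (km^3),
#'   `boot_std` (km^3), per-event matrix `event_values`, `n_events`.
#' @export
composite_delta_volume <- function(events, indices, fit, neutral, traits,
                                   geom, lags = -12:12, domain = NULL,
                                   mode = c("composite_state", "event_mean"),
                                   n_boot = 10000, boot_frac = 0.5,
                                   seed = 1L) {
  mode <- match.arg(mode)
  ev <- events$events
  if (!nrow(ev))
    return(structure(list(lag = lags, mean = rep(NA_real_, length(lags)),
                          boot_std = rep(NA_real_, length(lags)),
                          event_values = NULL, n_events = 0L),
                     class = "composite_result"))
  v_neutral <- .state_volume(neutral, traits, geom, domain)
  dv_of <- function(E, C) {
    st <- reconstruct_enso_state(neutral, fit, E, C)
    .state_volume(st, traits, geom, domain) - v_neutral
  }
  nt <- ncol(indices$E)
  evals <- matrix(NA_real_, nrow(ev), length(lags))
  for (i in seq_len(nrow(ev))) {
    peak <- which(indices$year == ev$season[i] & indices$month == 1L)
    tt <- peak + lags
    ok <- tt >= 1 & tt <= nt
    for (l in which(ok))
      evals[i, l] <- dv_of(indices$E[ev$member[i], tt[l]],
                           indices$C[ev$member[i], tt[l]])
  }
  if (mode == "composite_state") {
    comp <- composite_index_series(events, indices, lags)
    mean_dv <- vapply(seq_along(lags), function(l)
      if (comp$n[l] > 0) dv_of(comp$E[l], comp$C[l]) else NA_real_,
      numeric(1))
  } else {
    mean_dv <- colMeans(evals, na.rm = TRUE)
  }
  bs <- if (nrow(ev) >= 2)
    bootstrap_std(evals, n_boot = n_boot, frac = boot_frac, seed = seed)
  else rep(NA_real_, length(lags))
  structure(list(lag = lags, mean = mean_dv, boot_std = bs,
                 event_values = evals, n_events = nrow(ev),
                 type = paste(unique(ev$type), collapse = "+"),
                 trait = traits$label, mode = mode),
            class = "composite_result")
}

#' @export
print.composite_result <- function(x, ...) {
  if (x$n_events == 0) { cat("composite_result: empty event set\n"); return(invisible(x)) }
  ipeak <- which(x$lag == 0)
  cat(sprintf("composite_result [%s, %s traits]: %d events, peak dV = %.4g +/- %.3g km^3\n",
              x$type, x$trait, x$n_events, x$mean[ipeak], x$boot_std[ipeak]))
  invisible(x)
}

#' @export
plot.composite_result <- function(x, ...) {
  if (x$n_events == 0) stop("nothing to plot: empty composite")
  ylim <- range(c(x$mean - x$boot_std, x$mean + x$boot_std), na.rm = TRUE)
  plot(x$lag, x$mean, type = "l", lwd = 2, ylim = ylim,
       xlab = "months to peak", ylab = expression(Delta * V ~ (km^3)),
       main = sprintf("Composite habitat change (%s, %s)", x$type, x$trait),
       ...)
  ok <- is.finite(x$boot_std)
  polygon(c(x$lag[ok], rev(x$lag[ok])),
          c((x$mean - x$boot_std)[ok], rev((x$mean + x$boot_std)[ok])),
          col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Bootstrap standard deviation of event composites
#'
#' Resamples subsets of events (by default half the events, drawn with
#' replacement), recomputes the composite mean of each subset, and returns
#' the standard deviation across `n_boot` such composites - per lag when
#' `event_values` is an events x lags matrix. Deterministic for a given
#' seed. For i.i.d. values with standard deviation s the result approaches
#' s / sqrt(n/2).
#'
#' @param event_values numeric vector (one value per event) or matrix
#'   `[event, lag]`.
#' @param n_boot number of bootstrap composites (default 10000).
#' @param frac subset size as a fraction of the number of events.
#' @param replace draw with replacement (default TRUE).
#' @param seed RNG seed.
#' @return standard deviation(s) of the composite mean: scalar or
#'   per-column vector.
#' @export
bootstrap_std <- function(event_values, n_boot = 10000, frac = 0.5,
                          replace = TRUE, seed = 1L) {
  m <- if (is.matrix(event_values)) event_values else cbind(event_values)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 events to bootstrap")
  k <- max(1L, round(frac * n))
  set.seed(seed)
  idx <- matrix(sample.int(n, k * n_boot, replace = replace), nrow = n_boot)
  out <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    sd(rowMeans(matrix(v[idx], nrow = n_boot), na.rm = TRUE))
  }, numeric(1))
  if (is.matrix(event_values)) out else out[[1]]
}

#' Phase-integrated habitat change of one series
#'
#' Sum of monthly habitat-volume changes over a phase window (cumulated
#' monthly km^3, reported as km^3).
#'
#' @param delta_series numeric vector of monthly values.
#' @param phase_window `c(start, end)` indices into `delta_series`.
#' @return the windowed sum.
#' @export
phase_integral <- function(delta_series, phase_window) {
  s <- phase_window[1]; e <- phase_window[2]
  if (s < 1 || e > length(delta_series) || s > e)
    stop("phase window outside the series")
  sum(delta_series[s:e])
}

#' Per-event phase-integrated habitat changes
#'
#' For every event, reconstructs the monthly states over the event's phase
#' window (months where the standardised index magnitude stays above the
#' phase threshold) and sums the monthly habitat-volume changes.
#'
#' @inheritParams composite_delta_volume
#' @return a data frame with one row per event: `member`, `season`,
#'   `type`, `phase_months`, `integral` (km^3).
#' @export
event_phase_integrals <- function(events, indices, fit, neutral, traits,
                                  geom, domain = NULL) {
  ev <- events$events
  v_neutral <- .state_volume(neutral, traits, geom, domain)
  res <- numeric(nrow(ev)); nmon <- integer(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    tt <- ev$phase_start[i]:ev$phase_end[i]
    dv <- vapply(tt, function(t) {
      st <- reconstruct_enso_state(neutral, fit,
                                   indices$E[ev$member[i], t],
                                   indices$C[ev$member[i], t])
      .state_volume(st, traits, geom, domain) - v_neutral
    }, numeric(1))
    res[i] <- sum(dv); nmon[i] <- length(tt)
  }
  data.frame(member = ev$member, season = ev$season, type = ev$type,
             phase_months = nmon, integral = res)
}

#' Decadal frequency of ENSO events
#'
#' Total number of events divided by the number of member-decades:
#' count / (n_members * years / 10), per event type.
#'
#' @param events an [detect_events()] result.
#' @param n_members ensemble size the events were detected in.
#' @param years length of the record in years.
#' @return named numeric vector (events per decade) for EP_EN, CP_EN, LN.
#' @export
event_frequency <- function(events, n_members, years) {
  if (years <= 0 || n_members <= 0) stop("period and ensemble must be non-empty")
  cnt <- events$counts
  out <- as.numeric(cnt) / (n_members * years / 10)
  names(out) <- names(cnt)
  out
}

#' Frequency-weighted cumulative habitat impact
#'
#' Multiplies the phase-integrated habitat change of each ENSO type by its
#' decadal frequency of occurrence, giving the expected cumulative habitat
#' change per decade and member.
#'
#' @param phase_integrals named numeric vector, km^3 per event (e.g. mean
#'   of [event_phase_integrals()] by type).
#' @param frequencies named numeric vector, events per decade
#'   (see [event_frequency()]); names must match.
#' @return named vector, km^3 per decade.
#' @export
frequency_weighted_impact <- function(phase_integrals, frequencies) {
  if (!setequal(names(phase_integrals), names(frequencies)))
    stop("event types of phase integrals and frequencies do not match")
  phase_integrals * frequencies[names(phase_integrals)]
}

#' Period-mean surface warming
#'
#' Area-weighted (cosine-latitude) mean surface temperature (shallowest
#' model level) difference between two periods of an ensemble, averaged
#' over months and members.
#'
#' @param x an [ocean_ensemble()] with absolute fields.
#' @param period `c(first, last)` years of the target period.
#' @param reference `c(first, last)` years of the reference period.
#' @return warming, degC (positive = `period` warmer).
#' @export
warming_level <- function(x, period, reference) {
  stopifnot(inherits(x, "ocean_ensemble"))
  for (p in list(period, reference))
    if (p[1] < min(x$year) || p[2] > max(x$year))
      stop("period outside the record")
  surf <- x$fields$T[, , 1, , , drop = TRUE]   # [member, time, lat, lon]
  if (length(dim(surf)) == 3) dim(surf) <- c(1, dim(surf))
  w <- cos(x$lat * pi / 180)
  W <- array(rep(rep(w, each = prod(dim(surf)[1:2])), times = length(x$lon)),
             dim = dim(surf))
  pm <- function(p) {
    it <- x$year >= p[1] & x$year <= p[2]
    sum((surf * W)[, it, , ]) / sum(W[, it, , ])
  }
  pm(period) - pm(reference)
}

#' Decompose a habitat change into oxygen- and temperature-driven parts
#'
#' Counterfactual substitution: the habitat-volume change is recomputed
#' with only the pO2 anomaly applied (temperature neutral), only the
#' temperature anomaly applied (pO2 neutral), and with both. Fractions are
#' reported relative to the full change, together with the non-additive
#' residual full - (pO2-only + T-only).
#'
#' @param neutral a [neutral_climatology()] state with `pO2` and `T`.
#' @param fit a [fit_teleconnection()] model with `pO2` and `T`.
#' @param E_val,C_val index values of the ENSO state.
#' @param traits a [physio_traits()] object.
#' @param geom a [grid_geometry()].
#' @param domain optional analysis domain.
#' @return a list: `full`, `po2_only`, `t_only`, `residual` (km^3),
#'   `frac_po2`, `frac_t` (relative to `full`; `NA` with `undefined = TRUE`
#'   when `full` is 0).
#' @export
driver_decomposition <- function(neutral, fit, E_val, C_val, traits, geom,
                                 domain = NULL) {
  delta <- predict(fit, E = E_val, C = C_val)
  if (is.null(delta$pO2) || is.null(delta$T))
    stop("fit must include pO2 and T coefficients")
  v0 <- .state_volume(neutral, traits, geom, domain)
  mk_state <- function(dp, dt) {
    f <- neutral$fields
    f$pO2 <- pmax(f$pO2 + dp, 0)
    f$T <- f$T + dt
    st <- neutral; st$fields <- f; st
  }
  v_full <- .state_volume(mk_state(delta$pO2, delta$T), traits, geom, domain) - v0
  v_po2 <- .state_volume(mk_state(delta$pO2, 0), traits, geom, domain) - v0
  v_t <- .state_volume(mk_state(0, delta$T), traits, geom, domain) - v0
  undefined <- v_full == 0
  list(full = v_full, po2_only = v_po2, t_only = v_t,
       residual = v_full - (v_po2 + v_t),
       frac_po2 = if (undefined) NA_real_ else v_po2 / v_full,
       frac_t = if (undefined) NA_real_ else v_t / v_full,
       undefined = undefined)
}

#' Sweep the temperature-sensitivity trait E0
#'
#' Re-evaluates an analysis metric over a grid of E0 values (within the
#' measured span [-0.1, 0.9] eV), keeping all other traits fixed.
#'
#' @param traits base [physio_traits()].
#' @param e0_values numeric grid of E0 values, eV.
#' @param metric_fn function taking a `physio_traits` object and returning
#'   a named numeric vector.
#' @return a data frame with column `E0` and one column per metric.
#' @export
e0_sweep <- function(traits, e0_values, metric_fn) {
  if (any(e0_values < -0.1 | e0_values > 0.9))
    stop("E0 values outside the supported range [-0.1, 0.9] eV")
  rows <- lapply(e0_values, function(e0) {
    tr <- physio_traits("custom", A0 = traits$A0, E0 = e0,
                        T_ref = traits$T_ref, B = traits$B, n = traits$n)
    c(E0 = e0, metric_fn(tr))
  })
  as.data.frame(do.call(rbind, rows))
}

#' E0 sweep of the oxygen-versus-temperature driver balance
#'
#' Runs [driver_decomposition()] across an E0 grid and reports the
#' crossover: the smallest E0 at which the temperature-only habitat change
#' exceeds the oxygen-only change in magnitude (`NA` when temperature
#' never dominates on the grid).
#'
#' @inheritParams driver_decomposition
#' @param e0_values numeric grid of E0 values, eV.
#' @return a list: `sweep` (data frame E0, full, po2_only, t_only) and
#'   `crossover_e0`.
#' @export
e0_sweep_drivers <- function(neutral, fit, E_val, C_val, traits, geom,
                             e0_values = seq(-0.1, 0.9, by = 0.1),
                             domain = NULL) {
  sw <- e0_sweep(traits, e0_values, function(tr) {
    d <- driver_decomposition(neutral, fit, E_val, C_val, tr, geom, domain)
    c(full = d$full, po2_only = d$po2_only, t_only = d$t_only)
  })
  dom <- abs(sw$t_only) > abs(sw$po2_only)
  list(sweep = sw,
       crossover_e0 = if (any(dom)) min(sw$E0[dom]) else NA_real_)
}

#' Attribute habitat change to climate change versus El Nino
#'
#' Classifies every cell whose suitability differs between the historical
#' neutral state, the future neutral state and the future El Nino state
#' into one of six combinations of gain/loss driven by climate change (CC:
#' future neutral vs historical neutral) and/or El Nino (EN: future EN vs
#' future neutral): `+CC+EN`, `+CC-EN`, `-CC+EN`, `-CC-EN`, `CC_only`,
#' `EN_only`. Fractions are the changed volume in each class divided by
#' the total changed volume, so they lie in [0, 1] and sum to 1.
#'
#' @param hist_neutral,fut_neutral [neutral_climatology()] states for the
#'   historical and future periods.
#' @param fut_fit a [fit_teleconnection()] model for the future period.
#' @param E_val,C_val El Nino index values to reconstruct in the future
#'   climate.
#' @param traits a [physio_traits()] object.
#' @param geom a [grid_geometry()].
#' @param domain optional analysis domain.
#' @return a list: `fractions` (named, sums to 1), `volumes` (km^3 per
#'   class), `total_changed` (km^3) and `empty` (TRUE when no cell
#'   changed).
#' @export
cc_en_fractions <- function(hist_neutral, fut_neutral, fut_fit, E_val, C_val,
                            traits, geom, domain = NULL) {
  s_h <- suitability_mask(hist_neutral$fields$pO2, hist_neutral$fields$T, traits)
  s_f <- suitability_mask(fut_neutral$fields$pO2, fut_neutral$fields$T, traits)
  st_e <- reconstruct_enso_state(fut_neutral, fut_fit, E_val, C_val)
  s_e <- suitability_mask(st_e$fields$pO2, st_e$fields$T, traits)
  dm <- .domain_mask(geom, domain)
  dcc <- (s_f - s_h) * dm
  den <- (s_e - s_f) * dm
  classes <- c("+CC+EN", "+CC-EN", "-CC+EN", "-CC-EN", "CC_only", "EN_only")
  vols <- c(sum(geom$volume[dcc > 0 & den > 0]),
            sum(geom$volume[dcc > 0 & den < 0]),
            sum(geom$volume[dcc < 0 & den > 0]),
            sum(geom$volume[dcc < 0 & den < 0]),
            sum(geom$volume[dcc != 0 & den == 0]),
            sum(geom$volume[dcc == 0 & den != 0]))
  names(vols) <- classes
  total <- sum(vols)
  fr <- if (total > 0) vols / total else structure(rep(NA_real_, 6),
                                                   names = classes)
  list(fractions = fr, volumes = vols, total_changed = total,
       empty = total == 0)
}
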