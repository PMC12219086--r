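#' Monthly anomalies of an ensemble
#'
#' Removes the cross-member monthly climatology from every field and then,
#' depending on `mode`, either the ensemble mean at each time step
#' (`"ensemble_mean"`, the default: in externally forced runs this strips
#' the forced signal, including any secular trend, and isolates internal
#' variability; requires at least two members), a per-member linear trend
#' in time (`"linear_detrend"`), or nothing further (`"climatology"`).
#'
#' @param x an [ocean_ensemble()] with absolute fields.
#' @param mode anomaly baseline, see Details.
#' @return an [ocean_ensemble()] of anomalies (all fields and SST).
#' @export
compute_anomalies <- function(x, mode = c("ensemble_mean", "linear_detrend",
                                          "climatology")) {
  stopifnot(inherits(x, "ocean_ensemble"))
  mode <- match.arg(mode)
  if (mode == "ensemble_mean" && x$n_members < 2)
    stop("mode = 'ensemble_mean' needs at least 2 members")
  strip <- function(a) .anomalise(a, x$month, mode)
  x$fields <- lapply(x$fields, strip)
  x$SST <- strip(x$SST)
  x$anomaly <- TRUE
  x
}

# remove the monthly climatology and the chosen baseline from an array
# [member, time, ...]. For linear_detrend the per-member fit includes the
# month intercepts jointly with the trend, so a record that is exactly
# climatology + linear trend leaves zero anomalies.
.anomalise <- function(a, month, mode) {
  d <- dim(a)
  M <- d[1]; nt <- d[2]
  mat <- matrix(a, nrow = M * nt)         # rows ordered member-fastest
  if (mode == "linear_detrend") {
    tt <- seq_len(nt)
    X <- cbind(stats::model.matrix(~ 0 + factor(month)), tt)
    XtXi <- solve(crossprod(X))
    for (m in seq_len(M)) {
      rows <- m + (tt - 1L) * M
      Y <- mat[rows, , drop = FALSE]
      mat[rows, ] <- Y - X %*% (XtXi %*% crossprod(X, Y))
    }
    return(array(mat, dim = d))
  }
  row_month <- rep(month, each = M)
  clim <- rowsum(mat, row_month) / as.vector(table(row_month))
  mat <- mat - clim[row_month, , drop = FALSE]
  if (mode == "ensemble_mean") {
    grp <- rep(seq_len(nt), each = M)
    em <- rowsum(mat, grp) / M
    mat <- mat - em[grp, , drop = FALSE]
  }
  array(mat, dim = d)
}

# ONDJF seasonal means of a [member, time] series; the season spanning
# Oct(y)..Feb(y+1) is labelled y+1 (the year of the January peak)
.ondjf_means <- function(series, year, month) {
  years <- sort(unique(year))
  season_years <- years[-1]
  vals <- matrix(NA_real_, nrow = nrow(series), ncol = length(season_years))
  for (i in seq_along(season_years)) {
    ys <- season_years[i]
    idx <- which((year == ys - 1 & month >= 10) | (year == ys & month <= 2))
    vals[, i] <- rowMeans(series[, idx, drop = FALSE])
  }
  list(values = vals, season_years = season_years)
}

#' Nino-3.4 index from SST anomalies
#'
#' Area-weighted (cosine-latitude) mean SST anomaly over the Nino-3.4 box
#' (5S-5N, 170W-120W), as a monthly series per member plus October-February
#' (ONDJF) seasonal means labelled by the year of the January. The
#' standardising s.d. is computed from the pooled ONDJF values over the
#' reference period.
#'
#' @param x an anomaly [ocean_ensemble()] whose SST grid covers the box.
#' @param ref_period optional `c(first, last)` calendar years over which
#'   the standardising s.d. is computed (default: the whole record).
#' @return a list of class `"nino34"`: `monthly` `[member, time]` (degC),
#'   `ondjf` `[member, season]` (degC), `season_years`, `sd_ref` (degC) and
#'   `sd_monthly` (degC).
#' @export
nino34_index <- function(x, ref_period = NULL) {
  stopifnot(inherits(x, "ocean_ensemble"))
  if (!isTRUE(x$anomaly))
    warning("nino34_index expects anomalies; call compute_anomalies() first")
  monthly <- .box_mean(x$SST, x$sst_lat, x$sst_lon, c(-5, 5), c(-170, -120))
  ond <- .ondjf_means(monthly, x$year, x$month)
  in_ref <- if (is.null(ref_period)) rep(TRUE, length(ond$season_years))
            else ond$season_years >= ref_period[1] & ond$season_years <= ref_period[2]
  if (!any(in_ref)) stop("reference period outside the record")
  sd_ref <- sd(as.vector(ond$values[, in_ref, drop = FALSE]))
  in_ref_m <- if (is.null(ref_period)) rep(TRUE, length(x$year))
              else x$year >= ref_period[1] & x$year <= ref_period[2]
  structure(list(monthly = monthly, ondjf = ond$values,
                 season_years = ond$season_years,
                 sd_ref = sd_ref,
                 sd_monthly = sd(as.vector(monthly[, in_ref_m, drop = FALSE])),
                 year = x$year, month = x$month),
            class = "nino34")
}

#' EOF-based E and C indices of tropical Pacific SST variability
#'
#' Computes the first two EOFs of area-weighted monthly SST anomalies over
#' the tropical Pacific (120E-290E, 10N-10S), pooled across members, and
#' rotates the standardised principal components into the E (Eastern
#' Pacific) and C (Central Pacific) indices:
#' `E = (PC1 + PC2)/sqrt(2)`, `C = (PC1 - PC2)/sqrt(2)` - an exact
#' orthogonal rotation, so `PC1^2 + PC2^2 = E^2 + C^2` at every time.
#'
#' Sign conventions: EOF1 is oriented so PC1 co-varies positively with the
#' Nino-3.4 index; EOF2 is oriented so the E combination (not C) loads
#' maximally in the far-eastern Pacific, making E > 0 during Eastern
#' Pacific warm events.
#'
#' @param x an anomaly [ocean_ensemble()].
#' @param ref_period optional years for the Nino-3.4 standardising s.d.
#' @return an object of class `"ec_indices"`: standardised `pc1`, `pc2`,
#'   `E`, `C` (`[member, time]`), EOF regression patterns (degC per s.d. of
#'   PC), explained variance fractions, and the embedded [nino34_index()].
#' @export
eof_ec_indices <- function(x, ref_period = NULL) {
  stopifnot(inherits(x, "ocean_ensemble"))
  n34 <- nino34_index(x, ref_period)
  d <- dim(x$SST)
  M <- d[1]; nt <- d[2]; nla <- d[3]; nlo <- d[4]
  if (nla * nlo < 2) stop("need at least 2 spatial degrees of freedom")
  if (nt < 24) stop("need at least 24 months for the EOF analysis")
  mat <- matrix(x$SST, nrow = M * nt)            # [(m t) x cell], member-fastest
  w <- rep(cos(x$sst_lat * pi / 180), times = nlo)
  mw <- sweep(mat, 2, sqrt(w), `*`)
  sv <- svd(mw, nu = 2, nv = 2)
  if (sv$d[2] < 1e-10 * sv$d[1])
    stop("degenerate SST covariance: fewer than 2 resolvable modes")
  pcs <- sv$u %*% diag(sv$d[1:2])                # raw PCs, pooled
  pcs <- sweep(pcs, 2, apply(pcs, 2, sd), `/`)   # unit variance
  # regression patterns in degC per unit (standardised, unit-variance) PC
  pat <- crossprod(mat, pcs) / (nrow(mat) - 1)
  # sign 1: PC1 positively tied to Nino-3.4
  n34v <- as.vector(n34$monthly)
  if (sum(n34v * pcs[, 1]) < 0) { pcs[, 1] <- -pcs[, 1]; pat[, 1] <- -pat[, 1] }
  # sign 2: the E pattern, not C, must peak in the far-eastern Pacific
  fareast <- rep(x$sst_lat >= -5 & x$sst_lat <= 5, times = nlo) &
    rep(x$sst_lon >= -90 & x$sst_lon <= -70, each = nla)
  e_load <- mean((pat[fareast, 1] + pat[fareast, 2]) / sqrt(2))
  c_load <- mean((pat[fareast, 1] - pat[fareast, 2]) / sqrt(2))
  if (e_load < c_load) { pcs[, 2] <- -pcs[, 2]; pat[, 2] <- -pat[, 2] }
  pc1 <- matrix(pcs[, 1], M, nt); pc2 <- matrix(pcs[, 2], M, nt)
  varexp <- (sv$d^2 / sum(svd(mw, nu = 0, nv = 0)$d^2))[1:2]
  structure(list(pc1 = pc1, pc2 = pc2,
                 E = (pc1 + pc2) / sqrt(2), C = (pc1 - pc2) / sqrt(2),
                 patterns = list(eof1 = matrix(pat[, 1], nla, nlo),
                                 eof2 = matrix(pat[, 2], nla, nlo)),
                 varexp = varexp, nino34 = n34,
                 year = x$year, month = x$month,
                 sst_lat = x$sst_lat, sst_lon = x$sst_lon),
            class = "ec_indices")
}

#' @export
print.ec_indices <- function(x, ...) {
  cat(sprintf("ec_indices: %d member(s) x %d months; EOF1/EOF2 explain %.1f%% / %.1f%% of variance\n",
              nrow(x$pc1), ncol(x$pc1), 100 * x$varexp[1], 100 * x$varexp[2]))
  cat(sprintf("  ONDJF Nino-3.4 reference s.d.: %.3f degC\n", x$nino34$sd_ref))
  invisible(x)
}

# threshold classification shared by the detection stage and the synthetic
# truth calendar: warm if ONDJF Nino-3.4 >= thr_en s.d., cold if <= thr_ln;
# warm events split EP vs CP by E >= C at the peak season (ties -> EP)
.classify_events <- function(ondjf, season_years, sd_ref, ondE, ondC,
                             thr_en = 1.5, thr_ln = -0.5) {
  std <- ondjf / sd_ref
  out <- list()
  for (m in seq_len(nrow(std))) {
    for (i in seq_along(season_years)) {
      v <- std[m, i]
      if (is.na(v)) next
      if (v >= thr_en) {
        type <- if (ondE[m, i] >= ondC[m, i]) "EP_EN" else "CP_EN"
      } else if (v <= thr_ln) {
        type <- "LN"
      } else next
      out[[length(out) + 1L]] <- data.frame(
        member = m, season = season_years[i], type = type,
        peak_nino34_sd = v, peak_E = ondE[m, i], peak_C = ondC[m, i])
    }
  }
  if (!length(out))
    return(data.frame(member = integer(), season = integer(),
                      type = character(), peak_nino34_sd = numeric(),
                      peak_E = numeric(), peak_C = numeric()))
  do.call(rbind, out)
}

#' Detect and classify ENSO events
#'
#' Warm events are ONDJF seasons whose Nino-3.4 index reaches at least
#' `threshold_en` reference s.d.; cold events (La Nina) fall at or below
#' `threshold_ln` s.d. Warm events are split into Eastern-Pacific
#' (`EP_EN`, E >= C at the peak season; ties go to EP) and Central-Pacific
#' (`CP_EN`) El Nino. Each event also carries its phase window: the
#' contiguous run of months around the January peak during which the
#' magnitude of the monthly standardised index stays above
#' `phase_threshold` s.d.
#'
#' @param indices an [eof_ec_indices()] result.
#' @param threshold_en warm threshold, s.d. units (default 1.5).
#' @param threshold_ln cold threshold, s.d. units (default -0.5).
#' @param phase_threshold phase-window threshold, s.d. units (default 0.5).
#' @return an object of class `"enso_events"`: a data frame of events
#'   (member, season, type, peak values, phase window as time indices) plus
#'   counts by type and the thresholds used.
#' @export
detect_events <- function(indices, threshold_en = 1.5, threshold_ln = -0.5,
                          phase_threshold = 0.5) {
  stopifnot(inherits(indices, "ec_indices"))
  n34 <- indices$nino34
  if (is.null(n34$sd_ref) || !is.finite(n34$sd_ref) || n34$sd_ref <= 0)
    stop("no usable reference s.d. in the indices")
  ondE <- .ondjf_means(indices$E, indices$year, indices$month)
  ondC <- .ondjf_means(indices$C, indices$year, indices$month)
  ev <- .classify_events(n34$ondjf, n34$season_years, n34$sd_ref,
                         ondE$values, ondC$values,
                         thr_en = threshold_en, thr_ln = threshold_ln)
  if (nrow(ev)) {
    mstd <- n34$monthly / n34$sd_ref
    win <- t(vapply(seq_len(nrow(ev)), function(i) {
      .phase_window(mstd[ev$member[i], ], indices$year, indices$month,
                    ev$season[i], phase_threshold)
    }, numeric(2)))
    ev$phase_start <- win[, 1]; ev$phase_end <- win[, 2]
  } else {
    ev$phase_start <- integer(); ev$phase_end <- integer()
  }
  structure(list(events = ev,
                 counts = table(factor(ev$type, levels = c("EP_EN", "CP_EN", "LN"))),
                 thresholds = c(en = threshold_en, ln = threshold_ln,
                                phase = phase_threshold),
                 sd_ref = n34$sd_ref,
                 year = indices$year, month = indices$month),
            class = "enso_events")
}

# contiguous run of months with |standardised index| > thr containing the
# January peak of the labelled season; returns c(start, end) time indices
.phase_window <- function(mstd, year, month, season_year, thr) {
  peak <- which(year == season_year & month == 1L)
  if (!length(peak)) peak <- length(mstd)
  above <- abs(mstd) > thr
  s <- e <- peak
  if (above[peak]) {
    while (s > 1 && above[s - 1]) s <- s - 1
    while (e < length(mstd) && above[e + 1]) e <- e + 1
  }
  c(s, e)
}

#' @export
print.enso_events <- function(x, ...) {
  cat(sprintf("enso_events: %d events (thresholds: EN >= %.2g s.d., LN <= %.2g s.d.)\n",
              nrow(x$events), x$thresholds[["en"]], x$thresholds[["ln"]]))
  print(x$counts)
  invisible(x)
}

#' Subset an event set by type
#'
#' @param x an [detect_events()] result.
#' @param type one or more of `"EP_EN"`, `"CP_EN"`, `"LN"`.
#' @return an `"enso_events"` object containing only the requested types.
#' @export
subset_events <- function(x, type) {
  stopifnot(inherits(x, "enso_events"))
  x$events <- x$events[x$events$type %in% type, , drop = FALSE]
  x$counts <- table(factor(x$events$type, levels = c("EP_EN", "CP_EN", "LN")))
  x
}

#' Lag composites of the E and C indices across events
#'
#' Aligns the monthly E and C series of each event on its January peak
#' (lag 0) and averages across events at each lag; lags reaching outside
#' the record are dropped from the average for that event.
#'
#' @param events an [detect_events()] (or [subset_events()]) result.
#' @param indices the [eof_ec_indices()] the events were detected from.
#' @param lags integer vector of month offsets relative to the peak.
#' @return a data frame with columns `lag`, `E`, `C`, `n` (events
#'   contributing at that lag); zero rows if the event set is empty.
#' @export
composite_index_series <- function(events, indices, lags = -12:12) {
  stopifnot(inherits(events, "enso_events"), inherits(indices, "ec_indices"))
  ev <- events$events
  if (!nrow(ev))
    return(data.frame(lag = integer(), E = numeric(), C = numeric(),
                      n = integer()))
  nt <- ncol(indices$E)
  acc_E <- acc_C <- acc_n <- numeric(length(lags))
  for (i in seq_len(nrow(ev))) {
    peak <- which(indices$year == ev$season[i] & indices$month == 1L)
    tt <- peak + lags
    ok <- tt >= 1 & tt <= nt
    acc_E[ok] <- acc_E[ok] + indices$E[ev$member[i], tt[ok]]
    acc_C[ok] <- acc_C[ok] + indices$C[ev$member[i], tt[ok]]
    acc_n[ok] <- acc_n[ok] + 1
  }
  data.frame(lag = lags, E = acc_E / pmax(acc_n, 1),
             C = acc_C / pmax(acc_n, 1), n = as.integer(acc_n))
}
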