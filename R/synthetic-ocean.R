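#' Configuration for the synthetic ocean-ensemble generator
#'
#' Defines a south-east-Pacific-like test ocean with fully known ground
#' truth: two orthogonal tropical SST modes (an Eastern-Pacific pattern with
#' maximal loading in the far-eastern Pacific and a Central-Pacific dipole
#' with maximal loading in the central Pacific), stochastic principal
#' components with warm-skewed amplitudes and longer-persisting cold states,
#' subsurface temperature/oxygen anomalies tied linearly to the E and C
#' indices through prescribed coefficient fields, an oxycline/oxygen-minimum
#' -zone mean state, and secular trends (surface warming calibrated to
#' period-mean targets of +0.6 and +1.7 degC for 2006-2050 and 2050-2100
#' relative to 1920-2005, basin deoxygenation with a coastal reoxygenation
#' band in the upper OMZ).
#'
#' The default is a desk-scale fixture (5 members, 50 years, 4-degree
#' horizontal resolution, 10 depth levels over 0-600 m) that runs in
#' seconds; the full-scale configuration (34 members, 1920-2100) is reached
#' by raising `n_members`/`years` and lowering `dx`.
#'
#' @param n_members ensemble size.
#' @param years record length in years (monthly resolution).
#' @param start_year first calendar year.
#' @param dx horizontal grid step, degrees.
#' @param n_depth number of depth levels over `0..depth_max` m.
#' @param depth_max deepest layer interface, m.
#' @param pc_process list: `gamma` (quadratic skew on the EP principal
#'   component), `rho_warm`/`rho_cold` (month-to-month persistence of the EP
#'   process in warm/cold states; `rho_cold > rho_warm` makes cold events
#'   linger), `rho_c` (persistence of the CP process).
#' @param pattern_amp peak amplitudes (degC per unit PC) of the EP and CP
#'   SST patterns, named vector `c(ep=, cp=)`.
#' @param teleconnection peak values of the subsurface coefficient fields,
#'   named vector `c(a_T=, b_T=, a_O2=, b_O2=)`: degC (T) or umol/kg (O2)
#'   per unit E (alpha) or C (beta) index.
#' @param warming_targets period-mean surface warming relative to 1920-2005,
#'   degC, named `c(beg = , end = )` for 2006-2050 and 2050-2100; the linear
#'   plus quadratic trend coefficients are solved exactly from these.
#' @param trend_scale multiplier on all secular trends (0 disables them).
#' @param o2_trend list: `rate` (umol/kg/yr, negative = deoxygenation),
#'   `zscale` (m), `reox_rate` (umol/kg/yr, coastal reoxygenation),
#'   `reox_depth`/`reox_zwidth` (m, centre/width of the reoxygenated band).
#' @param noise white-noise standard deviation per field, named vector
#'   `c(T=, S=, O2=, SST=)` (>= 0). The default SST pattern amplitude to
#'   noise ratio is 5.
#' @param pc_series optional list `list(pc1, pc2)` of `[member, time]`
#'   matrices overriding the stochastic PC process (used for algebraic
#'   identity tests).
#' @param seed integer RNG seed; (config, seed) fully determines the output.
#' @return an object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_members = 5, years = 50, start_year = 1980,
                             dx = 4, n_depth = 10, depth_max = 600,
                             pc_process = list(gamma = 0.35, rho_warm = 0.90,
                                               rho_cold = 0.94, rho_c = 0.85),
                             pattern_amp = c(ep = 2.0, cp = 1.2),
                             teleconnection = c(a_T = 1.5, b_T = 0.8,
                                                a_O2 = 8, b_O2 = 4),
                             warming_targets = c(beg = 0.6, end = 1.7),
                             trend_scale = 1,
                             o2_trend = list(rate = -0.08, zscale = 300,
                                             reox_rate = 0.2,
                                             reox_depth = 150, reox_zwidth = 80),
                             noise = c(T = 0.3, S = 0.05, O2 = 1.6, SST = 0.4),
                             pc_series = NULL, seed = 1L) {
  if (any(noise < 0)) stop("noise standard deviations must be non-negative")
  if (n_members < 1 || years < 2) stop("need at least 1 member and 2 years")
  lat <- seq(-50 + dx / 2, -5, by = dx)
  lon <- seq(-110 + dx / 2, -70, by = dx)
  # stretched vertical grid: finer near the surface where the oxycline and
  # habitat boundaries sit, coarser at depth (as in z-level ocean models)
  depth_bounds <- depth_max * seq(0, 1, length.out = n_depth + 1)^1.5
  depth <- (head(depth_bounds, -1) + tail(depth_bounds, -1)) / 2
  sst_lat <- seq(-10 + dx / 2, 10, by = dx)
  sst_lon_e <- seq(120 + dx / 2, 290, by = dx)       # degrees east 120..290
  sst_lon <- ((sst_lon_e + 180) %% 360) - 180        # package convention
  pat <- .make_eof_patterns(sst_lat, sst_lon, pattern_amp)
  trend <- .solve_warming_trend(warming_targets)
  cfg <- list(n_members = as.integer(n_members), years = as.integer(years),
              start_year = as.integer(start_year),
              lat = lat, lon = lon, depth = depth, depth_bounds = depth_bounds,
              sst_lat = sst_lat, sst_lon = sst_lon,
              pc_process = pc_process, pattern_amp = pattern_amp,
              patterns = pat, teleconnection = teleconnection,
              warming_targets = warming_targets, trend = trend,
              trend_scale = trend_scale, o2_trend = o2_trend,
              noise = noise, pc_series = pc_series, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic_config: %d members x %d yr from %d, grid %dx%dx%d (depth x lat x lon)\n",
              x$n_members, x$years, x$start_year,
              length(x$depth), length(x$lat), length(x$lon)))
  cat(sprintf("  SST pattern amplitudes (EP/CP): %g / %g degC; noise SST %g degC\n",
              x$pattern_amp[["ep"]], x$pattern_amp[["cp"]], x$noise[["SST"]]))
  cat(sprintf("  teleconnection peaks: a_T=%g b_T=%g degC, a_O2=%g b_O2=%g umol/kg\n",
              x$teleconnection[["a_T"]], x$teleconnection[["b_T"]],
              x$teleconnection[["a_O2"]], x$teleconnection[["b_O2"]]))
  invisible(x)
}

# Two orthogonal (area-weighted) SST patterns on the tropical grid.
# EP: broad Gaussian centred in the eastern Pacific, peak loading in the
# far east. CP: zonal dipole - central-Pacific Gaussian with an opposing
# far-eastern lobe - Gram-Schmidt orthogonalised against EP, rescaled to
# its peak amplitude, and oriented so the E = (PC1+PC2)/sqrt(2)
# combination (not C) is the one loading the far-eastern Pacific, the same
# sign convention the EOF analysis applies to recovered modes. With that
# orientation the dipole's central-Pacific extremum is negative, so warm
# Nino-3.4 seasons lean towards PC2 < 0, i.e. towards CP El Nino, which
# reproduces the observed excess of CP over EP warm events.
.make_eof_patterns <- function(sst_lat, sst_lon, amp) {
  lon_e <- (sst_lon %% 360)  # degrees east for distance along the band
  g <- function(x, c0, w) exp(-((x - c0) / w)^2)
  p1 <- outer(g(sst_lat, 0, 6), g(lon_e, 260, 40))
  p2 <- outer(g(sst_lat, 0, 8), g(lon_e, 185, 20)) -
    0.20 * outer(g(sst_lat, 0, 6), g(lon_e, 278, 15))
  w <- matrix(cos(sst_lat * pi / 180), nrow = length(sst_lat),
              ncol = length(sst_lon))
  ip <- function(a, b) sum(a * b * w)
  p2 <- p2 - ip(p2, p1) / ip(p1, p1) * p1
  p1 <- p1 / max(abs(p1)) * amp[["ep"]]
  p2 <- p2 / max(abs(p2)) * amp[["cp"]]
  fareast <- sst_lon >= -90 & sst_lon <= -70
  if (mean(p2[, fareast]) < 0) p2 <- -p2
  list(p1 = p1, p2 = p2)
}

# Linear + quadratic surface-warming polynomial w(y) = r*(y-1920) + q*(y-1920)^2
# with coefficients solved so the period means of w over 2006-2050 and
# 2050-2100 exceed the 1920-2005 mean by exactly the two targets.
.solve_warming_trend <- function(targets) {
  m <- function(years, p) mean((years - 1920)^p)
  H <- 1920:2005; B <- 2006:2050; E <- 2050:2100
  A <- rbind(c(m(B, 1) - m(H, 1), m(B, 2) - m(H, 2)),
             c(m(E, 1) - m(H, 1), m(E, 2) - m(H, 2)))
  coefs <- solve(A, c(targets[["beg"]], targets[["end"]]))
  list(r = coefs[1], q = coefs[2], zscale = 150)
}

#' Simulate the stochastic principal-component process
#'
#' The EP principal component is an AR(1) process with state-dependent
#' persistence (higher in the cold state, so cold excursions last longer)
#' passed through a quadratic transform `x + gamma*(x^2 - 1)` that skews
#' amplitudes toward strong warm events; the CP principal component is a
#' plain AR(1). Exposed so that the process moments (e.g. the skewness
#' target of the E index) can be estimated by direct Monte-Carlo.
#'
#' @param n number of monthly steps.
#' @param pc_process parameter list as in [synthetic_config()].
#' @return a list with numeric vectors `pc1` and `pc2`.
#' @export
simulate_pc_process <- function(n, pc_process = synthetic_config()$pc_process) {
  p <- pc_process
  x <- numeric(n); x[1] <- rnorm(1)
  innov <- rnorm(n)
  for (t in 2:n) {
    rho <- if (x[t - 1] >= 0) p$rho_warm else p$rho_cold
    x[t] <- rho * x[t - 1] + sqrt(1 - rho^2) * innov[t]
  }
  pc1 <- x + p$gamma * (x^2 - 1)
  y <- numeric(n); y[1] <- rnorm(1)
  innov2 <- rnorm(n)
  for (t in 2:n) y[t] <- p$rho_c * y[t - 1] + sqrt(1 - p$rho_c^2) * innov2[t]
  list(pc1 = pc1, pc2 = y)
}

#' Generate a synthetic ocean ensemble with known truth
#'
#' Builds monthly ensemble fields as
#' `mean state + secular trend + alpha * E + beta * C + white noise`,
#' where E and C derive from the realised principal components through the
#' exact orthogonal rotation `E = (PC1 + PC2)/sqrt(2)`,
#' `C = (PC1 - PC2)/sqrt(2)`, and the tropical SST field carries the two
#' planted orthogonal patterns scaled by the PCs. The returned truth object
#' records the realised PCs and E/C series, the planted event calendar
#' (derived from the noise-free Nino-3.4 index with the same ONDJF
#' thresholds the detection stage uses), the true coefficient fields and
#' the trend parameters. Identical (config, seed) reproduce identical
#' output.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `ensemble` (an [ocean_ensemble()]) and
#'   `truth` (class `"synthetic_truth"`).
#' @examples
#' out <- generate_ensemble(synthetic_config(n_members = 2, years = 12))
#' out$ensemble
#' @export
generate_ensemble <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  M <- config$n_members
  nyr <- config$years
  nt <- 12L * nyr
  year <- rep(config$start_year + seq_len(nyr) - 1L, each = 12L)
  month <- rep(1:12, nyr)
  yfrac <- year + (month - 0.5) / 12
  nz <- length(config$depth); nla <- length(config$lat); nlo <- length(config$lon)

  # --- principal components and true indices -------------------------------
  if (!is.null(config$pc_series)) {
    pc1 <- config$pc_series$pc1; pc2 <- config$pc_series$pc2
    if (!all(dim(pc1) == c(M, nt))) stop("pc_series matrices must be [member, time]")
  } else {
    pc1 <- matrix(0, M, nt); pc2 <- matrix(0, M, nt)
    for (m in seq_len(M)) {
      p <- simulate_pc_process(nt, config$pc_process)
      pc1[m, ] <- p$pc1; pc2[m, ] <- p$pc2
    }
    # make the planted modes exactly identifiable: orthogonalise the CP
    # series against the EP series (the EOF analysis returns strictly
    # uncorrelated PCs, so sample correlation between the planted PCs
    # would otherwise leak scale between E and C) and standardise both to
    # unit variance of the centred pooled series, the scale convention the
    # EOF stage applies to recovered PCs
    centre <- function(x) if (M >= 2) sweep(x, 2, colMeans(x)) else x - rowMeans(x)
    pc1 <- pc1 / sd(as.vector(centre(pc1)))
    p1c <- centre(pc1); p2c <- centre(pc2)
    pc2 <- pc2 - sum(p1c * p2c) / sum(p1c * p1c) * pc1
    pc2 <- pc2 / sd(as.vector(centre(pc2)))
  }
  E <- (pc1 + pc2) / sqrt(2)
  C <- (pc1 - pc2) / sqrt(2)

  # --- coefficient and mean-state fields -----------------------------------
  cf <- .truth_fields(config)

  # --- trends ---------------------------------------------------------------
  ts <- config$trend_scale
  w_surf <- ts * (config$trend$r * (yfrac - 1920) +
                    config$trend$q * (yfrac - 1920)^2)
  tz_T <- outer(w_surf, exp(-config$depth / config$trend$zscale)) # [t, z]
  ot <- config$o2_trend
  o2_tz <- ts * outer(yfrac - 1920, ot$rate * exp(-config$depth / ot$zscale))
  reox_z <- exp(-((config$depth - ot$reox_depth) / ot$reox_zwidth)^2)
  reox_lon <- exp(-((config$lon + 72) / 8)^2)   # confined along the coast
  # [t,z] part of the reoxygenation trend; longitude factor applied below
  reox_tz <- ts * outer(yfrac - 1920, ot$reox_rate * reox_z)

  expand_tz <- function(tz) {  # [t,z] -> [m,t,z,la,lo]
    a <- aperm(array(tz, dim = c(nt, nz, M)), c(3, 1, 2))
    array(a, dim = c(M, nt, nz, nla, nlo))
  }
  expand_cell <- function(cell) {  # [z,la,lo] -> [m,t,z,la,lo]
    array(rep(as.vector(cell), each = M * nt), dim = c(M, nt, nz, nla, nlo))
  }

  Tarr <- expand_cell(cf$Tbar) + expand_tz(tz_T) +
    outer(E, cf$alpha$T) + outer(C, cf$beta$T)
  O2arr <- expand_cell(cf$O2bar) + expand_tz(o2_tz) +
    outer(E, cf$alpha$O2) + outer(C, cf$beta$O2)
  # coastal reoxygenation: [t,z] trend modulated by a coastal longitude band
  lon_fac <- array(rep(reox_lon, each = M * nt * nz * nla),
                   dim = c(M, nt, nz, nla, nlo))
  O2arr <- O2arr + expand_tz(reox_tz) * lon_fac
  Sarr <- array(35, dim = c(M, nt, nz, nla, nlo))
  # tropical SST: planted orthogonal patterns scaled by the PCs, plus the
  # surface-warming trend shared with the subsurface domain
  SST <- outer(pc1, config$patterns$p1) + outer(pc2, config$patterns$p2) +
    array(rep(w_surf, each = M),
          dim = c(M, nt, length(config$sst_lat), length(config$sst_lon)))

  if (config$noise[["T"]] > 0)
    Tarr <- Tarr + rnorm(length(Tarr), 0, config$noise[["T"]])
  if (config$noise[["S"]] > 0)
    Sarr <- Sarr + rnorm(length(Sarr), 0, config$noise[["S"]])
  if (config$noise[["O2"]] > 0)
    O2arr <- O2arr + rnorm(length(O2arr), 0, config$noise[["O2"]])
  if (config$noise[["SST"]] > 0)
    SST <- SST + rnorm(length(SST), 0, config$noise[["SST"]])
  n_clip <- sum(O2arr < 0)
  if (n_clip > 0) O2arr[O2arr < 0] <- 0

  ens <- ocean_ensemble(Tarr, Sarr, O2arr, SST,
                        lat = config$lat, lon = config$lon,
                        depth = config$depth, depth_bounds = config$depth_bounds,
                        sst_lat = config$sst_lat, sst_lon = config$sst_lon,
                        year = year, month = month)
  attr(ens, "n_clipped_o2") <- n_clip

  truth <- .build_truth(config, pc1, pc2, E, C, cf, year, month)
  list(ensemble = ens, truth = truth)
}

# mean-state and teleconnection coefficient fields on the subsurface grid
.truth_fields <- function(config) {
  z <- config$depth; la <- config$lat; lo <- config$lon
  g <- function(x, c0, w) exp(-((x - c0) / w)^2)
  Tbar <- outer(4 + 14 * exp(-z / 120), matrix(1, length(la), length(lo))) +
    outer(2 * exp(-z / 150), outer(g(la, -8, 18), rep(1, length(lo))))
  dim(Tbar) <- c(length(z), length(la), length(lo))
  O2bar <- outer(235 * exp(-z / 90) + 70 * (1 - exp(-z / 350)),
                 matrix(1, length(la), length(lo))) -
    outer(115 * g(z, 220, 160), outer(g(la, -12, 16), g(lo, -78, 18)))
  dim(O2bar) <- c(length(z), length(la), length(lo))
  O2bar[O2bar < 5] <- 5
  # oxygen anomalies shut down as the mean state approaches anoxia, so the
  # planted signal respects O2 >= 0 instead of being truncated
  o2_atten <- O2bar / (O2bar + 15)
  tc <- config$teleconnection
  f_z <- g(z, 130, 140); g_zT <- exp(-z / 200)
  g_la <- g(la, -15, 15); g_la_b <- g(la, -18, 20)
  h_coast <- g(lo, -74, 10); h_broad <- g(lo, -85, 25)
  mk <- function(a, fz, fla, flo) {
    out <- outer(fz, outer(fla, flo)) * a
    dim(out) <- c(length(z), length(la), length(lo))
    out
  }
  list(Tbar = Tbar, O2bar = O2bar,
       alpha = list(T = mk(tc[["a_T"]], g_zT, g_la, h_coast),
                    O2 = mk(tc[["a_O2"]], f_z, g_la, h_coast) * o2_atten),
       beta = list(T = mk(tc[["b_T"]], g_zT, g_la_b, h_broad),
                   O2 = mk(tc[["b_O2"]], f_z, g_la_b, h_broad) * o2_atten))
}

# Planted event calendar from the noise-free Nino-3.4 index: project the
# planted patterns onto the box, remove the cross-member mean (the same
# internal-variability baseline the detection stage uses by default), take
# ONDJF means and apply the standard thresholds.
.build_truth <- function(config, pc1, pc2, E, C, cf, year, month) {
  M <- nrow(pc1)
  w <- cos(config$sst_lat * pi / 180)
  inbox_la <- config$sst_lat >= -5 & config$sst_lat <= 5
  inbox_lo <- config$sst_lon >= -170 & config$sst_lon <= -120
  boxmean <- function(p) {
    sub <- p[inbox_la, inbox_lo, drop = FALSE]
    sum(sub * w[inbox_la]) / (sum(w[inbox_la]) * sum(inbox_lo))
  }
  p1b <- boxmean(config$patterns$p1)
  p2b <- boxmean(config$patterns$p2)
  centre <- function(x) {
    if (M >= 2) sweep(x, 2, colMeans(x)) else x - rowMeans(x)
  }
  pc1c <- centre(pc1); pc2c <- centre(pc2)
  n34 <- p1b * pc1c + p2b * pc2c
  Ec <- (pc1c + pc2c) / sqrt(2); Cc <- (pc1c - pc2c) / sqrt(2)
  ond <- .ondjf_means(n34, year, month)
  ondE <- .ondjf_means(Ec, year, month)
  ondC <- .ondjf_means(Cc, year, month)
  sd_ref <- sd(as.vector(ond$values))
  events <- .classify_events(ond$values, ond$season_years, sd_ref,
                             ondE$values, ondC$values)
  structure(list(pc1 = pc1, pc2 = pc2, E = E, C = C,
                 events = events, counts = table(factor(events$type,
                   levels = c("EP_EN", "CP_EN", "LN"))),
                 alpha = cf$alpha, beta = cf$beta,
                 mean_state = list(T = cf$Tbar, O2 = cf$O2bar),
                 patterns = config$patterns,
                 trend = config$trend, o2_trend = config$o2_trend,
                 trend_scale = config$trend_scale,
                 nino34_noisefree = n34, sd_ref = sd_ref,
                 season_years = ond$season_years,
                 config = config),
            class = "synthetic_truth")
}

#' Configured warming between two periods
#'
#' Evaluates the planted surface-warming polynomial of a synthetic truth at
#' a given depth and returns the difference of its period means - the value
#' the [warming_level()] estimator should recover up to noise.
#'
#' @param truth a `"synthetic_truth"` object.
#' @param period,reference `c(first, last)` calendar years.
#' @param depth depth of the measurement, m (0 = surface).
#' @return expected warming, degC.
#' @export
expected_warming <- function(truth, period, reference, depth = 0) {
  tr <- truth$trend
  w <- function(p) {
    y <- seq(p[1], p[2]) + 0.5
    mean(tr$r * (y - 1920) + tr$q * (y - 1920)^2)
  }
  truth$trend_scale * (w(period) - w(reference)) * exp(-depth / tr$zscale)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth: planted event calendar\n")
  print(x$counts)
  cat(sprintf("  noise-free ONDJF Nino-3.4 s.d.: %.3f degC\n", x$sd_ref))
  invisible(x)
}
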