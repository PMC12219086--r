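# Anomalies, Nino-3.4, E/C indices and event detection.

test_that("anomaly baselines remove climatology, ensemble mean and trends", {
  fix <- default_fix()
  # a field identical across members and equal to its climatology -> zero
  M <- 3; nt <- 48
  cell <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  Tarr <- array(rep(as.vector(cell), each = M * nt), c(M, nt, 2, 3, 2))
  zero <- array(0, dim(Tarr))
  db <- c(0, 300, 600)
  ens <- ocean_ensemble(Tarr, zero, zero, array(0, c(M, nt, 3, 4)),
                        lat = c(-30, -20, -10), lon = c(-100, -90),
                        depth = c(150, 450), depth_bounds = db,
                        sst_lat = seq(-5, 5, length.out = 3),
                        sst_lon = seq(-150, -120, length.out = 4),
                        year = rep(2000:2003, each = 12), month = rep(1:12, 4))
  an <- compute_anomalies(ens, mode = "ensemble_mean")
  expect_equal(max(abs(an$fields$T)), 0)
  # climatology + linear trend, removed by per-member detrending
  trend <- outer(seq_len(nt) * 0.01, array(1, c(2, 3, 2)))
  ens2 <- ens
  ens2$fields$T <- Tarr + aperm(array(trend, c(nt, 2, 3, 2, M)), c(5, 1, 2, 3, 4))
  an2 <- compute_anomalies(ens2, mode = "linear_detrend")
  expect_lt(max(abs(an2$fields$T)), 1e-10)
  expect_error(compute_anomalies(
    generate_ensemble(synthetic_config(n_members = 1, years = 3))$ensemble,
    mode = "ensemble_mean"), "2 members")
  # recovered anomalies track the planted signal within the noise level
  an3 <- fix$an
  planted <- outer(sweep(fix$truth$E, 2, colMeans(fix$truth$E)),
                   fix$truth$alpha$T) +
    outer(sweep(fix$truth$C, 2, colMeans(fix$truth$C)), fix$truth$beta$T)
  resid <- an3$fields$T - planted
  expect_lt(sd(resid), 2 * fix$cfg$noise[["T"]])
})

test_that("Nino-3.4 is the cosine-weighted box mean with ONDJF labelling", {
  fix <- default_fix()
  x <- fix$an
  # constant +1 degC anomaly over the whole SST grid -> index exactly 1
  u <- x
  u$SST <- array(1, dim(x$SST))
  n34 <- nino34_index(u)
  expect_equal(max(abs(n34$monthly - 1)), 0)
  expect_equal(max(abs(n34$ondjf - 1)), 0)
  # antisymmetric about the equator -> exact cancellation
  a <- x
  a$SST <- array(rep(sign(x$sst_lat), each = prod(dim(x$SST)[1:2])),
                 dim(x$SST))
  expect_lt(max(abs(nino34_index(a)$monthly)), 1e-12)
  # ONDJF value is the plain mean of the five monthly values
  n34 <- nino34_index(x)
  i <- which((x$year == 2000 & x$month >= 10) | (x$year == 2001 & x$month <= 2))
  expect_equal(n34$ondjf[3, n34$season_years == 2001],
               mean(n34$monthly[3, i]))
})

test_that("the E/C rotation is exact and preserves amplitude", {
  fix <- default_fix()
  ind <- fix$ind
  expect_equal(ind$E, (ind$pc1 + ind$pc2) / sqrt(2))
  expect_equal(ind$C, (ind$pc1 - ind$pc2) / sqrt(2))
  # PC1^2 + PC2^2 = E^2 + C^2 at every time
  expect_equal(ind$pc1^2 + ind$pc2^2, ind$E^2 + ind$C^2)
  # standardised PCs: unit variance, near-zero correlation
  expect_equal(sd(as.vector(ind$pc1)), 1, tolerance = 1e-6)
  expect_equal(sd(as.vector(ind$pc2)), 1, tolerance = 1e-6)
  expect_lt(abs(cor(as.vector(ind$pc1), as.vector(ind$pc2))), 1e-6)
  expect_equal(var(as.vector(ind$E)) + var(as.vector(ind$C)), 2,
               tolerance = 1e-4)
})

test_that("planted orthogonal patterns are recovered by the EOF analysis", {
  fix <- default_fix()
  p <- fix$cfg$patterns
  expect_gt(abs(cor(as.vector(p$p1), as.vector(fix$ind$patterns$eof1))), 0.99)
  expect_gt(abs(cor(as.vector(p$p2), as.vector(fix$ind$patterns$eof2))), 0.99)
  # sign convention: E combination loads the far-eastern Pacific
  fe <- fix$ind$sst_lon >= -90 & fix$ind$sst_lon <= -70
  epat <- (fix$ind$patterns$eof1 + fix$ind$patterns$eof2) / sqrt(2)
  cpat <- (fix$ind$patterns$eof1 - fix$ind$patterns$eof2) / sqrt(2)
  expect_gt(mean(epat[, fe]), mean(cpat[, fe]))
})

test_that("a single strong warm season yields exactly one EP event", {
  nt <- 20 * 12
  pc1 <- matrix(0, 1, nt)
  # ONDJF of the season labelled year 11: strong, far above threshold
  i <- which((rep(1:20, each = 12) == 10 & rep(1:12, 20) >= 10) |
               (rep(1:20, each = 12) == 11 & rep(1:12, 20) <= 2))
  pc1[1, i] <- 3
  cfg <- synthetic_config(n_members = 1, years = 20, trend_scale = 0,
                          noise = c(T = 0, S = 0, O2 = 0, SST = 0.05),
                          pc_series = list(pc1 = pc1, pc2 = matrix(0, 1, nt)))
  out <- generate_ensemble(cfg)
  an <- compute_anomalies(out$ensemble, mode = "climatology")
  ev <- detect_events(eof_ec_indices(an))
  expect_identical(as.integer(ev$counts[["EP_EN"]]), 1L)
  expect_identical(as.integer(ev$counts[["LN"]]), 0L)
  expect_equal(ev$events$season, cfg$start_year + 10)
})

test_that("no events are detected in a flat record", {
  fix <- default_fix()
  quiet <- fix$an
  set.seed(5)
  quiet$SST <- array(rnorm(length(quiet$SST), 0, 0.05), dim(quiet$SST))
  ev <- detect_events(eof_ec_indices(quiet), threshold_en = 10,
                      threshold_ln = -10)
  expect_identical(nrow(ev$events), 0L)
  cs <- composite_index_series(ev, fix$ind)
  expect_identical(nrow(cs), 0L)
})

test_that("planted events are detected with high precision and recall", {
  fix <- default_fix()
  tk <- with(fix$truth$events, paste(member, season, type))
  dk <- with(fix$ev$events, paste(member, season, type))
  expect_gte(mean(tk %in% dk), 0.9)   # recall
  expect_gte(mean(dk %in% tk), 0.9)   # precision
  # EP El Nino specifically: at least 90% of planted events found
  te <- fix$truth$events[fix$truth$events$type == "EP_EN", ]
  de <- fix$ev$events[fix$ev$events$type == "EP_EN", ]
  expect_gte(mean(paste(te$member, te$season) %in%
                    paste(de$member, de$season)), 0.9)
  # detection is reproducible
  ev2 <- detect_events(fix$ind)
  expect_identical(ev2$events, fix$ev$events)
})

test_that("cold events outnumber extreme EP warm events in skewed runs", {
  fix <- default_fix()
  cnt <- fix$ev$counts
  expect_gt(cnt[["LN"]], cnt[["EP_EN"]])
  expect_gt(cnt[["CP_EN"]], cnt[["EP_EN"]])
})

test_that("index composites average event series lag by lag", {
  fix <- default_fix()
  ev1 <- fix$ev
  ev1$events <- ev1$events[1, , drop = FALSE]
  cs <- composite_index_series(ev1, fix$ind, lags = -3:3)
  peak <- which(fix$ind$year == ev1$events$season &
                  fix$ind$month == 1L)
  expect_equal(cs$E, fix$ind$E[ev1$events$member, peak + (-3:3)])
  # two events -> pointwise mean
  ev2 <- fix$ev
  ev2$events <- ev2$events[1:2, , drop = FALSE]
  cs2 <- composite_index_series(ev2, fix$ind, lags = 0)
  p2 <- which(fix$ind$year == ev2$events$season[2] & fix$ind$month == 1L)
  expect_equal(cs2$E, mean(c(fix$ind$E[ev2$events$member[1], peak],
                             fix$ind$E[ev2$events$member[2], p2])))
})
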