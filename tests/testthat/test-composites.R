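# Event-level statistics: composites, bootstrap, phase integrals,
# frequencies, warming levels, driver decomposition, attribution.

test_that("bootstrap std is deterministic, zero for constants, and scales as s/sqrt(n/2)", {
  expect_equal(bootstrap_std(rep(3.5, 20), n_boot = 500, seed = 2), 0)
  v <- rnorm(30)
  expect_identical(bootstrap_std(v, n_boot = 200, seed = 9),
                   bootstrap_std(v, n_boot = 200, seed = 9))
  # analytic sampling-theory oracle for i.i.d. normals
  set.seed(10)
  n <- 40; s <- 2
  vals <- rnorm(n, 0, s)
  bs <- bootstrap_std(vals, n_boot = 10000, seed = 1)
  expect_lt(abs(bs - sd(vals) / sqrt(n / 2)) / (sd(vals) / sqrt(n / 2)), 0.05)
  # ten times more resamples changes the estimate by < 2%
  bs10 <- bootstrap_std(vals, n_boot = 100000, seed = 1)
  expect_lt(abs(bs10 - bs) / bs, 0.02)
  expect_error(bootstrap_std(1.0), "at least 2")
})

test_that("phase integrals sum the windowed series", {
  expect_equal(phase_integral(c(5, 7, 9), c(2, 2)), 7)
  # symmetric triangular series: closed-form triangular number
  tri <- c(1:5, 4:1)
  expect_equal(phase_integral(tri, c(1, 9)), 25)
  expect_error(phase_integral(tri, c(0, 5)), "outside")
  expect_error(phase_integral(tri, c(5, 20)), "outside")
  # temporal asymmetry: a longer cold event with equal peak outweighs a
  # shorter warm one in cumulated magnitude
  warm <- c(2, 4, 2); cold <- -c(1, 2, 4, 4, 3, 2, 1)
  expect_gt(abs(phase_integral(cold, c(1, 7))),
            abs(phase_integral(warm, c(1, 3))))
})

test_that("event frequencies are per member-decade", {
  ev <- structure(list(counts = c(EP_EN = 10, CP_EN = 0, LN = 4)),
                  class = "enso_events")
  f <- event_frequency(ev, n_members = 1, years = 50)
  expect_equal(unname(f), c(2.0, 0, 0.8))
  f2 <- event_frequency(structure(list(counts = c(EP_EN = 20, CP_EN = 0,
                                                  LN = 8)),
                                  class = "enso_events"),
                        n_members = 2, years = 50)
  expect_equal(unname(f2), c(2.0, 0, 0.8))   # doubling members, same rate
  expect_error(event_frequency(ev, 1, 0), "non-empty")
})

test_that("frequency weighting multiplies impacts by occurrence rates", {
  pi_ <- c(EP_EN = -100, CP_EN = -100, LN = 50)
  fr <- c(EP_EN = 1, CP_EN = 3, LN = 3)
  w <- frequency_weighted_impact(pi_, fr)
  expect_equal(unname(w["CP_EN"] / w["EP_EN"]), 3)
  expect_equal(unname(frequency_weighted_impact(c(LN = 77), c(LN = 0))), 0)
  expect_error(frequency_weighted_impact(pi_, c(EP_EN = 1)), "match")
  # cold events at ~3x the frequency overcome a larger per-event impact
  fix <- default_fix()
  fr_fix <- event_frequency(fix$ev, fix$cfg$n_members, fix$cfg$years)
  expect_gt(fr_fix[["LN"]] / fr_fix[["EP_EN"]], 3)
})

test_that("warming levels recover the planted trend", {
  fixc <- century_fix()
  # reference = period -> exactly zero
  expect_equal(warming_level(fixc$ens, c(1950, 1980), c(1950, 1980)), 0)
  # clean linearity check: a trend-only record (indices zeroed) recovers
  # the configured polynomial exactly up to measurement noise
  M <- 2; nt <- 80 * 12
  cfg0 <- synthetic_config(n_members = M, years = 80, start_year = 1980,
                           n_depth = 4,
                           noise = c(T = 0.05, S = 0, O2 = 0.1, SST = 0.05),
                           pc_series = list(pc1 = matrix(0, M, nt),
                                            pc2 = matrix(0, M, nt)))
  out0 <- generate_ensemble(cfg0)
  got <- warming_level(out0$ensemble, c(2030, 2059), c(1980, 2009))
  want <- expected_warming(out0$truth, c(2030, 2059), c(1980, 2009),
                           depth = out0$ensemble$depth[1])
  expect_equal(got, want, tolerance = 0.01)
  # default study conditions: mid- and late-century warming close to the
  # configured +0.6 / +1.7 degC surface targets (attenuated to the top
  # model level), within internal-variability tolerance
  for (p in list(c(2006, 2050), c(2050, 2100))) {
    m <- warming_level(fixc$ens, p, c(1920, 2005))
    e <- expected_warming(fixc$truth, p, c(1920, 2005),
                          depth = fixc$ens$depth[1])
    expect_equal(m, e, tolerance = 0.12)
  }
  expect_error(warming_level(fixc$ens, c(2150, 2160), c(1920, 2005)),
               "outside")
})

test_that("composite habitat change has the planted sign structure", {
  fix <- default_fix()
  tr <- physio_traits("MHT")
  warm <- composite_delta_volume(subset_events(fix$ev, "EP_EN"), fix$ind,
                                 fix$fit, fix$neutral, tr, fix$geom,
                                 lags = -6:6, n_boot = 500)
  cold <- composite_delta_volume(subset_events(fix$ev, "LN"), fix$ind,
                                 fix$fit, fix$neutral, tr, fix$geom,
                                 lags = -6:6, n_boot = 500)
  expect_gt(warm$mean[warm$lag == 0], 0)   # warm events gain habitat
  expect_lt(cold$mean[cold$lag == 0], 0)   # cold events lose habitat
  expect_true(all(warm$boot_std >= 0, na.rm = TRUE))
  # single event: the composite equals that event's trajectory
  one <- subset_events(fix$ev, "EP_EN")
  one$events <- one$events[1, , drop = FALSE]
  co1 <- composite_delta_volume(one, fix$ind, fix$fit, fix$neutral, tr,
                                fix$geom, lags = -2:2, n_boot = 100)
  expect_equal(co1$mean, as.vector(co1$event_values[1, ]))
  # empty event set signals emptiness
  none <- subset_events(fix$ev, "EP_EN")
  none$events <- none$events[0, , drop = FALSE]
  co0 <- composite_delta_volume(none, fix$ind, fix$fit, fix$neutral, tr,
                                fix$geom)
  expect_identical(co0$n_events, 0L)
  expect_true(all(is.na(co0$mean)))
})

test_that("extreme warm composites outweigh cold ones across the trait set", {
  fix <- default_fix()
  peak <- function(type, lab) {
    co <- composite_delta_volume(subset_events(fix$ev, type), fix$ind,
                                 fix$fit, fix$neutral, physio_traits(lab),
                                 fix$geom, lags = -6:6, n_boot = 100)
    max(abs(co$mean), na.rm = TRUE)
  }
  labs <- c("HHT", "MHT", "LHT")
  ep <- sum(vapply(labs, peak, numeric(1), type = "EP_EN"))
  ln <- sum(vapply(labs, peak, numeric(1), type = "LN"))
  expect_gt(ep, ln)
})

test_that("oxygen dominates the habitat response in the planted regime", {
  fix <- default_fix()
  dd <- driver_decomposition(fix$neutral, fix$fit, 2, 1,
                             physio_traits("MHT"), fix$geom)
  expect_gt(dd$full, 0)
  expect_gt(dd$frac_po2, 0.5)
  expect_equal(dd$residual, dd$full - dd$po2_only - dd$t_only)
  # temperature-only term vanishes when the fit has no T response
  fit0 <- fix$fit
  fit0$coefficients$T$alpha[] <- 0
  fit0$coefficients$T$beta[] <- 0
  dd0 <- driver_decomposition(fix$neutral, fit0, 2, 1, physio_traits("MHT"),
                              fix$geom)
  expect_equal(dd0$t_only, 0)
  expect_equal(dd0$frac_po2, 1)
  expect_equal(dd0$residual, 0)
  # no anomalies at all: undefined fractions, flagged
  ddn <- driver_decomposition(fix$neutral, fix$fit, 0, 0,
                              physio_traits("MHT"), fix$geom)
  expect_true(ddn$undefined)
  expect_true(is.na(ddn$frac_po2))
})

test_that("the temperature contribution grows with E0 from zero", {
  fix <- default_fix()
  # LHT's shallow boundary sits in the strongly warmed layer: the
  # temperature-only change grows monotonically with E0 there
  swl <- e0_sweep_drivers(fix$neutral, fix$fit, 2, 1, physio_traits("LHT"),
                          fix$geom, e0_values = seq(0, 0.9, by = 0.15))
  expect_equal(swl$sweep$t_only[swl$sweep$E0 == 0], 0)
  expect_true(all(diff(abs(swl$sweep$t_only)) >= 0))
  # for the mid-tolerance archetype the growth holds overall even though
  # whole-cell counting makes individual steps jumpy
  sw <- e0_sweep_drivers(fix$neutral, fix$fit, 2, 1, physio_traits("MHT"),
                         fix$geom, e0_values = seq(0, 0.9, by = 0.15))
  expect_equal(sw$sweep$t_only[sw$sweep$E0 == 0], 0)
  expect_gt(abs(sw$sweep$t_only[nrow(sw$sweep)]), abs(sw$sweep$t_only[2]))
  # consistency: the sweep at the base E0 equals the direct computation
  sw2 <- e0_sweep(physio_traits("MHT"), c(0.34), function(tr)
    c(full = driver_decomposition(fix$neutral, fix$fit, 2, 1, tr,
                                  fix$geom)$full))
  expect_equal(sw2$full,
               driver_decomposition(fix$neutral, fix$fit, 2, 1,
                                    physio_traits("MHT"), fix$geom)$full)
  expect_error(e0_sweep(physio_traits("MHT"), c(0, 1.5), identity), "range")
})

test_that("climate-change versus El Nino fractions sum to one and match a sign-table oracle", {
  fixc <- century_fix()
  ensc <- fixc$ens
  hist_n <- neutral_climatology(ensc, c(1921, 2005), label = "HIST")
  fut_n <- neutral_climatology(ensc, c(2050, 2100), label = "END_21C")
  tr <- physio_traits("MHT")
  fr <- cc_en_fractions(hist_n, fut_n, fixc$fit, 2, 1, tr, fixc$geom)
  expect_false(fr$empty)
  expect_equal(sum(fr$fractions), 1)
  expect_true(all(fr$fractions >= 0 & fr$fractions <= 1))
  # explicit per-cell classification oracle
  s_h <- suitability_mask(hist_n$fields$pO2, hist_n$fields$T, tr)
  st_e <- reconstruct_enso_state(fut_n, fixc$fit, 2, 1)
  s_f <- suitability_mask(fut_n$fields$pO2, fut_n$fields$T, tr)
  s_e <- suitability_mask(st_e$fields$pO2, st_e$fields$T, tr)
  dm <- ensohab:::.domain_mask(fixc$geom, NULL)
  vols <- c(0, 0, 0, 0, 0, 0)
  for (i in which(dm)) {
    dcc <- s_f[i] - s_h[i]; den <- s_e[i] - s_f[i]
    k <- if (dcc > 0 && den > 0) 1 else if (dcc > 0 && den < 0) 2
      else if (dcc < 0 && den > 0) 3 else if (dcc < 0 && den < 0) 4
      else if (dcc != 0) 5 else if (den != 0) 6 else 0
    if (k > 0) vols[k] <- vols[k] + fixc$geom$volume[i]
  }
  expect_equal(unname(fr$volumes), vols)
  # no EN anomaly, CC-driven change only -> everything in the CC_only class
  fr2 <- cc_en_fractions(hist_n, fut_n, fixc$fit, 0, 0, tr, fixc$geom)
  expect_equal(unname(fr2$fractions["CC_only"]), 1)
  expect_equal(sum(fr2$volumes[names(fr2$volumes) != "CC_only"]), 0)
})

test_that("phase-integrated impacts reflect event duration", {
  fix <- default_fix()
  tr <- physio_traits("MHT")
  ep <- subset_events(fix$ev, "EP_EN")
  ph <- event_phase_integrals(ep, fix$ind, fix$fit, fix$neutral, tr, fix$geom)
  expect_identical(nrow(ph), nrow(ep$events))
  expect_true(all(ph$phase_months >= 1))
  expect_gt(mean(ph$integral), 0)
  ln <- subset_events(fix$ev, "LN")
  phl <- event_phase_integrals(ln, fix$ind, fix$fit, fix$neutral, tr, fix$geom)
  expect_lt(mean(phl$integral), 0)
})
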