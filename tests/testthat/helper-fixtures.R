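# Shared fixtures, built once per test run and cached.

.fix_cache <- new.env(parent = emptyenv())

# the default desk-scale study fixture with all pipeline stages
default_fix <- function() {
  if (is.null(.fix_cache$fix)) {
    cfg <- synthetic_config()
    gen <- generate_ensemble(cfg)
    ens <- add_po2(gen$ensemble)
    an <- compute_anomalies(ens)
    ind <- eof_ec_indices(an)
    ev <- detect_events(ind)
    fit <- fit_teleconnection(an, ind, vars = c("pO2", "T", "O2"))
    .fix_cache$fix <- list(cfg = cfg, truth = gen$truth, ens = ens, an = an,
                           ind = ind, ev = ev, fit = fit,
                           neutral = neutral_climatology(ens),
                           geom = grid_geometry(ens))
  }
  .fix_cache$fix
}

# long, thin fixture spanning both climate periods (for trends / attribution)
century_fix <- function() {
  if (is.null(.fix_cache$century)) {
    cfg <- synthetic_config(n_members = 4, years = 181, start_year = 1920,
                            n_depth = 6)
    gen <- generate_ensemble(cfg)
    ens <- add_po2(gen$ensemble)
    an <- compute_anomalies(ens)
    ind <- eof_ec_indices(an)
    fit <- fit_teleconnection(an, ind, vars = c("pO2", "T"))
    .fix_cache$century <- list(cfg = cfg, truth = gen$truth, ens = ens,
                               ind = ind, fit = fit,
                               geom = grid_geometry(ens))
  }
  .fix_cache$century
}

skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3

rel_rms <- function(est, tru) sqrt(mean((est - tru)^2)) / sqrt(mean(tru^2))

# small helper: a bare anomaly ensemble with prescribed index series and
# subsurface fields built as alpha*E + beta*C (+ noise)
make_linear_ensemble <- function(E, C, alpha, beta, noise = 0,
                                 nz = 3, nla = 4, nlo = 3) {
  M <- nrow(E); nt <- ncol(E)
  cell_a <- array(alpha, c(nz, nla, nlo))
  cell_b <- array(beta, c(nz, nla, nlo))
  Tarr <- outer(E, cell_a) + outer(C, cell_b)
  if (noise > 0) Tarr <- Tarr + array(rnorm(length(Tarr), 0, noise), dim(Tarr))
  zero <- array(0, dim(Tarr))
  sst <- array(0, c(M, nt, 3, 4))
  db <- seq(0, 600, length.out = nz + 1)
  ens <- ocean_ensemble(Tarr, zero, zero, sst,
                        lat = seq(-40, -10, length.out = nla),
                        lon = seq(-100, -80, length.out = nlo),
                        depth = (head(db, -1) + tail(db, -1)) / 2,
                        depth_bounds = db,
                        sst_lat = seq(-5, 5, length.out = 3),
                        sst_lon = seq(-150, -120, length.out = 4),
                        year = rep(seq_len(ceiling(nt / 12)), each = 12)[1:nt] + 1999,
                        month = rep(1:12, length.out = nt),
                        anomaly = TRUE)
  ens
}
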