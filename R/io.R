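#' Write an ensemble and its truth sidecar to disk
#'
#' Writes CF-style NetCDF: `ocean.nc` holds the subsurface fields
#' (dimensions member/time/depth/lat/lon, units attributes degC / PSU /
#' umol/kg) and the tropical SST field on its own grid; `truth.nc` holds
#' the planted teleconnection coefficient fields and realised principal
#' components; `events.csv` the planted event calendar and `truth.json`
#' the scalar truth (trend coefficients, reference s.d.). All floating
#' point data are stored in double precision, so a read round-trip
#' reproduces the values exactly.
#'
#' @param ensemble an [ocean_ensemble()].
#' @param truth the matching `"synthetic_truth"` (or `NULL` to skip the
#'   sidecar).
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(ensemble, truth, path) {
  x <- ensemble
  stopifnot(inherits(x, "ocean_ensemble"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dmem <- ncdf4::ncdim_def("member", "1", seq_len(x$n_members))
  dtime <- ncdf4::ncdim_def("time", "months since start", seq_along(x$year))
  ddep <- ncdf4::ncdim_def("depth", "m", x$depth)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", x$lat)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", x$lon)
  dslat <- ncdf4::ncdim_def("sst_lat", "degrees_north", x$sst_lat)
  dslon <- ncdf4::ncdim_def("sst_lon", "degrees_east", x$sst_lon)
  sub_dims <- list(dmem, dtime, ddep, dlat, dlon)
  units <- c(T = "degC", S = "PSU", O2 = "umol/kg", pO2 = "mbar")
  vars <- lapply(names(x$fields), function(v)
    ncdf4::ncvar_def(v, units[[v]], sub_dims, missval = 1e30, prec = "double"))
  names(vars) <- names(x$fields)
  vars$SST <- ncdf4::ncvar_def("SST", "degC", list(dmem, dtime, dslat, dslon),
                               missval = 1e30, prec = "double")
  vars$year <- ncdf4::ncvar_def("year", "1", list(dtime), prec = "integer")
  vars$month <- ncdf4::ncvar_def("month", "1", list(dtime), prec = "integer")
  vars$depth_bounds <- ncdf4::ncvar_def("depth_bounds", "m",
    list(ncdf4::ncdim_def("depth_bnds", "1", seq_along(x$depth_bounds))),
    prec = "double")
  nc <- ncdf4::nc_create(file.path(path, "ocean.nc"), vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (v in names(x$fields)) ncdf4::ncvar_put(nc, vars[[v]], x$fields[[v]])
  ncdf4::ncvar_put(nc, vars$SST, x$SST)
  ncdf4::ncvar_put(nc, vars$year, x$year)
  ncdf4::ncvar_put(nc, vars$month, x$month)
  ncdf4::ncvar_put(nc, vars$depth_bounds, x$depth_bounds)
  if (!is.null(truth)) .write_truth(truth, path, dmem, dtime, ddep, dlat, dlon)
  invisible(path)
}

.write_truth <- function(truth, path, dmem, dtime, ddep, dlat, dlon) {
  cdims <- list(ddep, dlat, dlon)
  pdims <- list(dmem, dtime)
  defs <- list(
    alpha_T = ncdf4::ncvar_def("alpha_T", "degC per index", cdims, prec = "double"),
    beta_T = ncdf4::ncvar_def("beta_T", "degC per index", cdims, prec = "double"),
    alpha_O2 = ncdf4::ncvar_def("alpha_O2", "umol/kg per index", cdims, prec = "double"),
    beta_O2 = ncdf4::ncvar_def("beta_O2", "umol/kg per index", cdims, prec = "double"),
    pc1 = ncdf4::ncvar_def("pc1", "1", pdims, prec = "double"),
    pc2 = ncdf4::ncvar_def("pc2", "1", pdims, prec = "double"))
  nc <- ncdf4::nc_create(file.path(path, "truth.nc"), defs)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, defs$alpha_T, truth$alpha$T)
  ncdf4::ncvar_put(nc, defs$beta_T, truth$beta$T)
  ncdf4::ncvar_put(nc, defs$alpha_O2, truth$alpha$O2)
  ncdf4::ncvar_put(nc, defs$beta_O2, truth$beta$O2)
  ncdf4::ncvar_put(nc, defs$pc1, truth$pc1)
  ncdf4::ncvar_put(nc, defs$pc2, truth$pc2)
  write.csv(truth$events, file.path(path, "events.csv"), row.names = FALSE)
  jsonlite::write_json(list(trend = truth$trend, o2_trend = truth$o2_trend,
                            trend_scale = truth$trend_scale,
                            sd_ref = truth$sd_ref, seed = truth$config$seed),
                       file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ocean ensemble from NetCDF
#'
#' Reads a fixture written by [write_fixture()] or any file with the same
#' dimension layout. Units are normalised to the package conventions:
#' temperatures with a Kelvin units attribute are converted to degC,
#' longitudes on [0, 360) are rotated to [-180, 180), and depth axes
#' stored deepest-first are flipped to increase downward (fields are
#' reordered to match). Cells flagged by the missing value become `NA`.
#'
#' @param path directory containing `ocean.nc`, or the file itself.
#' @param variables subsurface variables to require (default T, S, O2).
#' @return an [ocean_ensemble()].
#' @export
read_ocean_netcdf <- function(path, variables = c("T", "S", "O2")) {
  file <- if (dir.exists(path)) file.path(path, "ocean.nc") else path
  if (!file.exists(file)) stop("no such file: ", file)
  nc <- ncdf4::nc_open(file)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  have <- names(nc$var)
  missing_v <- setdiff(variables, have)
  if (length(missing_v))
    stop("missing variable(s) in file: ", paste(missing_v, collapse = ", "))
  getdim <- function(nm) as.vector(nc$dim[[nm]]$vals)
  depth <- getdim("depth"); lat <- getdim("lat"); lon <- getdim("lon")
  flip <- FALSE
  if (is.unsorted(depth)) { flip <- TRUE; depth <- rev(depth) }
  lon <- ((lon + 180) %% 360) - 180
  lon_ord <- order(lon)
  fields <- lapply(variables, function(v) {
    a <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
    u <- ncdf4::ncatt_get(nc, v, "units")$value
    if (v == "T" && is.character(u) && grepl("^(K|kelvin)", u, ignore.case = TRUE))
      a <- a - 273.15
    if (flip) a <- a[, , rev(seq_len(dim(a)[3])), , , drop = FALSE]
    a[, , , , lon_ord, drop = FALSE]
  })
  names(fields) <- variables
  sst <- ncdf4::ncvar_get(nc, "SST", collapse_degen = FALSE)
  sst_lat <- getdim("sst_lat")
  sst_lon <- ((getdim("sst_lon") + 180) %% 360) - 180
  year <- as.integer(ncdf4::ncvar_get(nc, "year"))
  month <- as.integer(ncdf4::ncvar_get(nc, "month"))
  db <- if ("depth_bounds" %in% have) as.vector(ncdf4::ncvar_get(nc, "depth_bounds"))
        else .infer_bounds(depth)
  ens <- ocean_ensemble(fields$T, fields$S, fields$O2, sst,
                        lat = lat, lon = lon[lon_ord], depth = depth,
                        depth_bounds = db,
                        sst_lat = sst_lat, sst_lon = sst_lon,
                        year = year, month = month)
  if ("pO2" %in% variables) ens$fields <- fields[variables]
  ens
}

.infer_bounds <- function(depth) {
  mid <- (head(depth, -1) + tail(depth, -1)) / 2
  c(max(0, depth[1] - (mid[1] - depth[1])), mid,
    depth[length(depth)] + (depth[length(depth)] - mid[length(mid)]))
}

#' Read a truth sidecar
#'
#' @param path directory written by [write_fixture()].
#' @return a list with the planted coefficient fields, PC series, event
#'   calendar and scalar truth.
#' @export
read_truth <- function(path) {
  nc <- ncdf4::nc_open(file.path(path, "truth.nc"))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  g <- function(v) ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
  scal <- jsonlite::read_json(file.path(path, "truth.json"), simplifyVector = TRUE)
  list(alpha = list(T = g("alpha_T"), O2 = g("alpha_O2")),
       beta = list(T = g("beta_T"), O2 = g("beta_O2")),
       pc1 = g("pc1"), pc2 = g("pc2"),
       events = read.csv(file.path(path, "events.csv")),
       trend = scal$trend, o2_trend = scal$o2_trend, sd_ref = scal$sd_ref)
}

#' Run the full habitat-change analysis pipeline
#'
#' Executes the stages in order on a synthetic configuration: generate the
#' ensemble, derive pO2, compute anomalies, E/C indices and events, fit the
#' teleconnection model, build the neutral climatology, and produce
#' per-type composite habitat changes, phase integrals and decadal
#' frequencies for each requested trait archetype. All randomness flows
#' from `config$seed` and the bootstrap seed, so a rerun with the same
#' configuration reproduces every number bit-identically.
#'
#' @param config a [synthetic_config()].
#' @param traits character vector of trait presets (default MHT).
#' @param anomaly_mode passed to [compute_anomalies()].
#' @param lags composite lags, months to peak.
#' @param n_boot,boot_seed bootstrap settings.
#' @param domain optional analysis domain.
#' @param keep_ensemble keep the (large) generated ensemble in the result.
#' @return an object of class `"ensohab_analysis"`.
#' @export
run_pipeline <- function(config, traits = "MHT",
                         anomaly_mode = "ensemble_mean",
                         lags = -12:12, n_boot = 10000, boot_seed = 1L,
                         domain = NULL, keep_ensemble = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  stage <- "generate"
  res <- tryCatch({
    gen <- generate_ensemble(config)
    ens <- add_po2(gen$ensemble)
    stage <- "anomalies"
    an <- compute_anomalies(ens, mode = anomaly_mode)
    stage <- "indices"
    ind <- eof_ec_indices(an)
    stage <- "events"
    evs <- detect_events(ind)
    stage <- "teleconnection"
    fit <- fit_teleconnection(an, ind, vars = c("pO2", "T"))
    stage <- "climatology"
    neutral <- neutral_climatology(ens)
    geom <- grid_geometry(ens)
    stage <- "composites"
    composites <- list()
    phase <- list()
    for (tr_label in traits) {
      tr <- physio_traits(tr_label)
      for (ty in c("EP_EN", "CP_EN", "LN")) {
        sub <- subset_events(evs, ty)
        if (!nrow(sub$events)) next
        key <- paste(tr_label, ty, sep = ".")
        composites[[key]] <- composite_delta_volume(
          sub, ind, fit, neutral, tr, geom, lags = lags, domain = domain,
          n_boot = n_boot, seed = boot_seed)
        phase[[key]] <- event_phase_integrals(sub, ind, fit, neutral, tr,
                                              geom, domain = domain)
      }
    }
    freq <- event_frequency(evs, config$n_members, config$years)
    list(truth = gen$truth, indices = ind, events = evs, fit = fit,
         neutral = neutral, geom = geom, composites = composites,
         phase_integrals = phase, frequencies = freq,
         ensemble = if (keep_ensemble) ens else NULL)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (check the configuration and inputs of that stage)",
                 stage, conditionMessage(e)), call. = FALSE)
  })
  res$provenance <- list(config_hash = .config_hash(config),
                         seed = config$seed, boot_seed = boot_seed,
                         traits = traits, anomaly_mode = anomaly_mode,
                         package_version = as.character(utils::packageVersion("ensohab")))
  class(res) <- "ensohab_analysis"
  res
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

#' @export
print.ensohab_analysis <- function(x, ...) {
  cat("ensohab_analysis\n")
  cat(sprintf("  config %s (seed %d), anomaly mode %s\n",
              substr(x$provenance$config_hash, 1, 8), x$provenance$seed,
              x$provenance$anomaly_mode))
  print(x$events$counts)
  cat("  events/decade: ", paste(sprintf("%s=%.2f", names(x$frequencies),
                                         x$frequencies), collapse = ", "), "\n")
  for (k in names(x$composites)) {
    co <- x$composites[[k]]
    i0 <- which(co$lag == 0)
    cat(sprintf("  %-12s peak dV = %10.4g +/- %.3g km^3 (n=%d)\n",
                k, co$mean[i0], co$boot_std[i0], co$n_events))
  }
  invisible(x)
}

#' @export
summary.ensohab_analysis <- function(object, ...) {
  ph <- do.call(rbind, lapply(names(object$phase_integrals), function(k) {
    p <- object$phase_integrals[[k]]
    data.frame(key = k, n = nrow(p), mean_phase_integral = mean(p$integral),
               mean_phase_months = mean(p$phase_months))
  }))
  structure(list(events = object$events$counts,
                 frequencies = object$frequencies, phase = ph),
            class = "summary.ensohab_analysis")
}

#' @export
print.summary.ensohab_analysis <- function(x, ...) {
  cat("Event counts:\n"); print(x$events)
  cat("Events per decade:\n"); print(round(x$frequencies, 3))
  cat("Phase-integrated habitat change (km^3):\n")
  print(x$phase, row.names = FALSE)
  invisible(x)
}
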