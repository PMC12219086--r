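#' Ensemble of gridded ocean fields
#'
#' Container for an ensemble of monthly ocean fields on a regular
#' latitude/longitude/depth grid: subsurface temperature, salinity and
#' dissolved oxygen as arrays with dimensions
#' `[member, time, depth, lat, lon]`, plus sea-surface temperature on its
#' own (tropical) grid with dimensions `[member, time, lat, lon]`.
#'
#' @param T,S,O2 subsurface fields `[member, time, depth, lat, lon]`:
#'   temperature (degC), salinity (PSU), dissolved oxygen (umol/kg).
#' @param SST sea-surface temperature `[member, time, lat, lon]` on the
#'   `sst_lat`/`sst_lon` grid (degC).
#' @param lat,lon subsurface cell-centre coordinates (degrees north / east,
#'   longitudes in [-180, 180)).
#' @param depth cell-centre depths, metres, strictly increasing.
#' @param depth_bounds layer interfaces, length `length(depth) + 1`.
#' @param sst_lat,sst_lon SST grid cell centres.
#' @param year,month calendar year and month (1-12) per time step.
#' @param anomaly logical: do the fields hold anomalies?
#' @return an object of class `"ocean_ensemble"`.
#' @export
ocean_ensemble <- function(T, S, O2, SST, lat, lon, depth, depth_bounds,
                           sst_lat, sst_lon, year, month, anomaly = FALSE) {
  if (is.unsorted(depth, strictly = TRUE)) stop("depth must be strictly increasing")
  if (length(depth_bounds) != length(depth) + 1L)
    stop("depth_bounds must have length(depth) + 1 entries")
  nt <- length(year)
  if (length(month) != nt) stop("year and month must have equal length")
  dT <- dim(T)
  if (length(dT) != 5L) stop("subsurface fields must be 5-d [member,time,depth,lat,lon]")
  expect <- c(dT[1], nt, length(depth), length(lat), length(lon))
  for (nm in c("T", "S", "O2")) {
    a <- get(nm, inherits = FALSE)
    if (!identical(dim(a), as.integer(expect)))
      stop(sprintf("field %s has dimensions inconsistent with the coordinates", nm))
  }
  if (!identical(dim(SST), as.integer(c(dT[1], nt, length(sst_lat), length(sst_lon)))))
    stop("SST dimensions inconsistent with the SST grid")
  structure(list(fields = list(T = T, S = S, O2 = O2), SST = SST,
                 lat = lat, lon = lon, depth = depth,
                 depth_bounds = depth_bounds,
                 sst_lat = sst_lat, sst_lon = sst_lon,
                 year = year, month = month,
                 n_members = dT[1], anomaly = anomaly),
            class = "ocean_ensemble")
}

#' @export
print.ocean_ensemble <- function(x, ...) {
  cat(sprintf("ocean_ensemble%s: %d member(s), %d months (%d-%d)\n",
              if (isTRUE(x$anomaly)) " (anomalies)" else "",
              x$n_members, length(x$year), min(x$year), max(x$year)))
  cat(sprintf("  subsurface grid: %d depth x %d lat x %d lon (%g-%g m, %g..%g N, %g..%g E)\n",
              length(x$depth), length(x$lat), length(x$lon),
              min(x$depth_bounds), max(x$depth_bounds),
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  cat(sprintf("  SST grid: %d lat x %d lon\n", length(x$sst_lat), length(x$sst_lon)))
  cat(sprintf("  fields: %s\n", paste(names(x$fields), collapse = ", ")))
  invisible(x)
}

#' Add an oxygen partial-pressure field to an ensemble
#'
#' Computes pO2 (mbar) cell-wise from the absolute dissolved oxygen,
#' temperature and salinity fields (see [partial_pressure()]) and stores it
#' as field `"pO2"`. Must be applied to absolute fields, not anomalies.
#'
#' @param x an [ocean_ensemble()] with absolute fields.
#' @return the ensemble with an added `pO2` field (mbar).
#' @export
add_po2 <- function(x) {
  stopifnot(inherits(x, "ocean_ensemble"))
  if (isTRUE(x$anomaly)) stop("pO2 must be computed from absolute fields, not anomalies")
  p <- .po2_mbar(x$fields$O2, x$fields$T, x$fields$S)
  x$fields$pO2 <- p
  x
}

#' Grid-cell geometry of an ensemble
#'
#' Cell volumes on the subsurface grid, computed as
#' R^2 cos(lat) dlat dlon dz with R = 6371 km and angles in radians;
#' volumes in km^3, identical for all longitudes at a given latitude.
#'
#' @param x an [ocean_ensemble()] (or a list with `lat`, `lon`, `depth`,
#'   `depth_bounds`).
#' @return a list of class `"grid_geometry"`: `volume` array
#'   `[depth, lat, lon]` (km^3), plus the coordinate vectors.
#' @export
grid_geometry <- function(x) {
  lat <- x$lat; lon <- x$lon; depth <- x$depth; db <- x$depth_bounds
  dlat <- diff(lat); dlon <- diff(lon)
  if (length(unique(round(dlat, 10))) > 1 || length(unique(round(dlon, 10))) > 1)
    stop("grid_geometry assumes regular horizontal spacing")
  dphi <- dlat[1] * pi / 180
  dlam <- dlon[1] * pi / 180
  dz_km <- diff(db) / 1000
  area_km2 <- .R_earth_km^2 * cos(lat * pi / 180) * dphi * dlam  # per lat
  vol <- array(0, dim = c(length(depth), length(lat), length(lon)))
  for (k in seq_along(depth))
    vol[k, , ] <- outer(area_km2 * dz_km[k], rep(1, length(lon)))
  structure(list(volume = vol, lat = lat, lon = lon, depth = depth,
                 depth_bounds = db), class = "grid_geometry")
}

# logical [depth, lat, lon] mask of cells whose centre lies in the domain box
.domain_mask <- function(geom, domain = NULL) {
  if (is.null(domain))
    domain <- list(depth = c(0, 600), lat = c(-50, -5), lon = c(-110, -70))
  ind <- outer(geom$depth >= domain$depth[1] & geom$depth <= domain$depth[2],
               geom$lat >= domain$lat[1] & geom$lat <= domain$lat[2], `&`)
  ink <- geom$lon >= domain$lon[1] & geom$lon <= domain$lon[2]
  m <- array(FALSE, dim = dim(geom$volume))
  for (j in which(ink)) m[, , j] <- ind
  m
}

# reshape [member, time, ...] field to [(member*time) x ncell]
.pool_mt <- function(a) {
  d <- dim(a)
  matrix(a, nrow = d[1] * d[2], ncol = prod(d[-(1:2)]))
}

# area-weighted (cos lat) mean of an SST-like array [member,time,lat,lon]
# over a lat/lon box; returns [member, time]
.box_mean <- function(a, lat, lon, lat_range, lon_range) {
  ila <- which(lat >= lat_range[1] & lat <= lat_range[2])
  ilo <- which(lon >= lon_range[1] & lon <= lon_range[2])
  if (!length(ila) || !length(ilo)) stop("box not covered by the grid")
  sub <- a[, , ila, ilo, drop = FALSE]
  w <- cos(lat[ila] * pi / 180)
  W <- array(rep(w, each = prod(dim(sub)[1:2])), dim = dim(sub))
  apply(sub * W, c(1, 2), sum) / sum(w * length(ilo))
}
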