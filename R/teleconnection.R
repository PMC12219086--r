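#' Fit the bilinear ENSO teleconnection model
#'
#' Fits, independently at every ocean grid cell, the bilinear regression
#' `anomaly(t) = alpha * E(t) + beta * C(t)` of a field's monthly anomalies
#' onto the E and C indices (no intercept: anomalies and indices are
#' centred by construction). Because E and C are orthogonal by
#' construction, alpha and beta coincide with the two univariate
#' projections; the fit is still computed from the full 2x2 normal
#' equations so that mildly correlated sample indices are handled exactly.
#'
#' @param x an anomaly [ocean_ensemble()] (see [compute_anomalies()]).
#' @param indices an [eof_ec_indices()] result on the same time axis, or a
#'   list with `[member, time]` matrices `E` and `C`.
#' @param vars which subsurface fields to fit (default all present, e.g.
#'   `c("T", "pO2")` after [add_po2()] + [compute_anomalies()]).
#' @return an object of class `"teleconnection_fit"` with, per variable,
#'   coefficient fields `alpha` and `beta` (`[depth, lat, lon]`, field
#'   units per unit index), standard errors, and the fraction of variance
#'   explained; supports [coef()], [predict()], [residuals()],
#'   [simulate()], `print()` and `summary()`.
#' @examples
#' \donttest{
#' out <- generate_ensemble(synthetic_config(n_members = 3, years = 20))
#' an <- compute_anomalies(add_po2(out$ensemble))
#' ind <- eof_ec_indices(an)
#' fit <- fit_teleconnection(an, ind, vars = c("T", "O2"))
#' fit
#' }
#' @export
fit_teleconnection <- function(x, indices, vars = NULL) {
  stopifnot(inherits(x, "ocean_ensemble"))
  if (!isTRUE(x$anomaly)) stop("fit_teleconnection expects anomaly fields")
  E <- indices$E; C <- indices$C
  if (!all(dim(E) == dim(x$fields[[1]])[1:2]))
    stop("indices and anomalies do not share the member/time axes")
  if (is.null(vars)) vars <- setdiff(names(x$fields), "S")
  Ev <- as.vector(E); Cv <- as.vector(C)
  X <- cbind(E = Ev, C = Cv)
  G <- crossprod(X)
  cn <- kappa(G)
  if (!is.finite(cn) || cn > 1e8)
    stop(sprintf("E and C are (near-)collinear: condition number %.3g", cn))
  Gi <- solve(G)
  dims <- dim(x$fields[[vars[1]]])[3:5]
  n <- length(Ev)
  res <- list()
  for (v in vars) {
    Y <- .pool_mt(x$fields[[v]])
    B <- Gi %*% crossprod(X, Y)              # 2 x ncell
    fitted <- X %*% B
    rss <- colSums((Y - fitted)^2)
    tss <- colSums(Y^2)
    sigma2 <- rss / max(n - 2, 1)
    res[[v]] <- list(alpha = array(B[1, ], dims),
                     beta = array(B[2, ], dims),
                     se_alpha = array(sqrt(sigma2 * Gi[1, 1]), dims),
                     se_beta = array(sqrt(sigma2 * Gi[2, 2]), dims),
                     r2 = array(ifelse(tss > 0, 1 - rss / tss, NA_real_), dims),
                     resid_var = array(sigma2, dims))
  }
  structure(list(coefficients = res, vars = vars, n = n,
                 E = E, C = C,
                 lat = x$lat, lon = x$lon, depth = x$depth,
                 depth_bounds = x$depth_bounds,
                 year = x$year, month = x$month),
            class = "teleconnection_fit")
}

#' @export
print.teleconnection_fit <- function(x, ...) {
  cat(sprintf("teleconnection_fit: %s ~ alpha*E + beta*C at %d cells, n = %d months\n",
              paste(x$vars, collapse = "/"),
              length(x$coefficients[[1]]$alpha), x$n))
  for (v in x$vars)
    cat(sprintf("  %-4s alpha in [%.3g, %.3g], beta in [%.3g, %.3g], median R2 = %.2f\n",
                v, min(x$coefficients[[v]]$alpha), max(x$coefficients[[v]]$alpha),
                min(x$coefficients[[v]]$beta), max(x$coefficients[[v]]$beta),
                median(x$coefficients[[v]]$r2, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.teleconnection_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$vars, function(v) {
    co <- object$coefficients[[v]]
    data.frame(var = v,
               alpha_min = min(co$alpha), alpha_max = max(co$alpha),
               beta_min = min(co$beta), beta_max = max(co$beta),
               median_r2 = median(co$r2, na.rm = TRUE),
               mean_resid_sd = mean(sqrt(co$resid_var)))
  }))
  structure(list(table = tab, n = object$n), class = "summary.teleconnection_fit")
}

#' @export
print.summary.teleconnection_fit <- function(x, ...) {
  cat(sprintf("Bilinear ENSO teleconnection fit (n = %d pooled months)\n", x$n))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.teleconnection_fit <- function(object, ...) {
  lapply(object$coefficients, function(co) list(alpha = co$alpha, beta = co$beta))
}

#' Predict anomaly fields for given index values
#'
#' @param object a [fit_teleconnection()] model.
#' @param E,C scalar index values.
#' @param ... unused.
#' @return a named list of `[depth, lat, lon]` anomaly fields, one per
#'   fitted variable: `alpha * E + beta * C`.
#' @export
predict.teleconnection_fit <- function(object, E = 0, C = 0, ...) {
  lapply(object$coefficients, function(co) co$alpha * E + co$beta * C)
}

#' @export
residuals.teleconnection_fit <- function(object, x, ...) {
  if (missing(x)) stop("supply the anomaly ensemble the model was fitted to")
  out <- list()
  for (v in object$vars) {
    pred <- outer(object$E, object$coefficients[[v]]$alpha) +
      outer(object$C, object$coefficients[[v]]$beta)
    out[[v]] <- x$fields[[v]] - pred
  }
  out
}

#' Simulate anomaly fields from a fitted teleconnection model
#'
#' Draws `nsim` synthetic anomaly snapshots `alpha*E + beta*C + noise` with
#' cell-wise Gaussian noise at the fitted residual variance.
#'
#' @param object a [fit_teleconnection()] model.
#' @param nsim number of snapshots.
#' @param seed optional RNG seed.
#' @param E,C index values recycled across snapshots.
#' @param ... unused.
#' @return a list (length `nsim`) of named lists of fields.
#' @export
simulate.teleconnection_fit <- function(object, nsim = 1, seed = NULL,
                                        E = 0, C = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  E <- rep_len(E, nsim); C <- rep_len(C, nsim)
  lapply(seq_len(nsim), function(i) {
    lapply(object$coefficients, function(co) {
      co$alpha * E[i] + co$beta * C[i] +
        array(rnorm(length(co$alpha), 0, sqrt(co$resid_var)), dim(co$alpha))
    })
  })
}

#' Neutral-state climatology of an ensemble
#'
#' The ENSO-neutral reference state of each field for a named period:
#' October-February means per season, then averaged over the period's
#' seasons and the ensemble members.
#'
#' @param x an [ocean_ensemble()] with absolute fields (after [add_po2()]
#'   if pO2 is needed downstream).
#' @param period `c(first, last)` calendar years (of the January labelling
#'   each season).
#' @param label optional period label (e.g. `"HIST"`).
#' @return an object of class `"neutral_state"`: one `[depth, lat, lon]`
#'   field per variable plus the grid coordinates and period.
#' @export
neutral_climatology <- function(x, period = NULL, label = "custom") {
  stopifnot(inherits(x, "ocean_ensemble"))
  if (isTRUE(x$anomaly)) stop("neutral_climatology expects absolute fields")
  dummy <- matrix(0, 1, length(x$year))
  seasons <- .ondjf_means(dummy, x$year, x$month)$season_years
  if (is.null(period)) period <- range(seasons)
  keep <- seasons >= period[1] & seasons <= period[2]
  if (!any(keep)) stop("period outside the record")
  fields <- lapply(x$fields, function(a) {
    d <- dim(a)
    acc <- array(0, d[3:5]); nacc <- 0
    for (ys in seasons[keep]) {
      idx <- which((x$year == ys - 1 & x$month >= 10) |
                     (x$year == ys & x$month <= 2))
      sub <- a[, idx, , , , drop = FALSE]
      acc <- acc + array(colMeans(matrix(sub, nrow = d[1] * length(idx))),
                         d[3:5])
      nacc <- nacc + 1
    }
    acc / nacc
  })
  structure(list(fields = fields, period = period, label = label,
                 lat = x$lat, lon = x$lon, depth = x$depth,
                 depth_bounds = x$depth_bounds),
            class = "neutral_state")
}

#' @export
print.neutral_state <- function(x, ...) {
  cat(sprintf("neutral_state [%s]: ONDJF climatology %d-%d, fields %s\n",
              x$label, x$period[1], x$period[2],
              paste(names(x$fields), collapse = ", ")))
  invisible(x)
}

#' Reconstruct an ENSO-state field from a neutral climatology
#'
#' Adds the teleconnection anomaly for given index values to the neutral
#' state: `field_ENSO = field_neutral + alpha * E + beta * C` for every
#' fitted variable. Reconstructed pO2 is floored at zero; the number of
#' clipped cells is recorded in attribute `"n_clipped"`.
#'
#' @param neutral a [neutral_climatology()] state.
#' @param fit a [fit_teleconnection()] model on the same grid.
#' @param E_val,C_val index values of the ENSO state to reconstruct.
#' @return an object of class `"enso_state"` (fields + coordinates).
#' @export
reconstruct_enso_state <- function(neutral, fit, E_val, C_val) {
  stopifnot(inherits(neutral, "neutral_state"),
            inherits(fit, "teleconnection_fit"))
  if (!isTRUE(all.equal(neutral$depth, fit$depth)) ||
      !isTRUE(all.equal(neutral$lat, fit$lat)) ||
      !isTRUE(all.equal(neutral$lon, fit$lon)))
    stop("neutral state and coefficients are on different grids")
  delta <- predict(fit, E = E_val, C = C_val)
  fields <- neutral$fields
  n_clip <- 0L
  for (v in names(delta)) {
    if (is.null(fields[[v]]))
      stop(sprintf("neutral state lacks variable '%s'", v))
    f <- fields[[v]] + delta[[v]]
    if (v == "pO2") {
      n_clip <- sum(f < 0)
      f[f < 0] <- 0
    }
    fields[[v]] <- f
  }
  structure(list(fields = fields, E = E_val, C = C_val,
                 period = neutral$period, label = neutral$label,
                 lat = neutral$lat, lon = neutral$lon,
                 depth = neutral$depth, depth_bounds = neutral$depth_bounds,
                 n_clipped = n_clip),
            class = "enso_state")
}

#' @export
print.enso_state <- function(x, ...) {
  cat(sprintf("enso_state: neutral [%s] + teleconnection at E = %.3g, C = %.3g\n",
              x$label, x$E, x$C))
  if (x$n_clipped > 0)
    cat(sprintf("  (%d reconstructed pO2 cells clipped at 0)\n", x$n_clipped))
  invisible(x)
}
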