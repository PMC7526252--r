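#' Fit a precipitation delta-2H isoscape by universal kriging
#'
#' Fits a spatial mixed model to per-station summer mean delta-2H: a fixed
#' mean surface linear in latitude, squared latitude and elevation, plus a
#' stationary isotropic Gaussian random field with exponential covariance
#' \deqn{C(d) = \sigma^2 e^{-d/\phi} + \tau^2 1(d = 0)}
#' where distances are great-circle kilometres. The covariance parameters
#' (partial sill \eqn{\sigma^2}, range \eqn{\phi}, nugget \eqn{\tau^2})
#' maximize the restricted likelihood (REML); the nugget-to-sill ratio and
#' range are profiled over a fixed multi-start grid so the fit is
#' deterministic for identical inputs.
#'
#' @param stations data.frame of station summaries as produced by
#'   [summarize_stations()]: columns \code{lon}, \code{lat},
#'   \code{elevation}, \code{mean_d2h} (and optionally \code{station_id}).
#' @param n_range_starts number of starting values for the range parameter
#'   (quantiles of the interstation distance distribution).
#' @param control list passed to [stats::optim()] for each start.
#' @return an object of class \code{"isoscape"}: fitted mean coefficients,
#'   covariance parameters, the training stations, and cached matrices for
#'   prediction. Supports \code{print}, \code{summary}, \code{coef},
#'   \code{vcov}, \code{residuals}, \code{fitted}, \code{logLik},
#'   \code{predict}, \code{simulate} and \code{plot}.
#' @seealso [predict.isoscape()], [isoscape_at()]
#' @export
fit_isoscape <- function(stations, n_range_starts = 4,
                         control = list(maxit = 500, reltol = 1e-10)) {
  need <- c("lon", "lat", "elevation", "mean_d2h")
  miss <- setdiff(need, names(stations))
  if (length(miss))
    stop("stations table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(stations)
  if (n < 10)
    stop("insufficient stations: need >= 10, got ", n, call. = FALSE)
  z <- parse_permil(stations$mean_d2h)
  if (any(!is.finite(z))) stop("non-finite station means", call. = FALSE)

  centers <- c(lat = mean(stations$lat), lat2 = mean(stations$lat^2),
               elevation = mean(stations$elevation))
  X <- cbind(`(Intercept)` = 1,
             lat = stations$lat - centers["lat"],
             lat2 = stations$lat^2 - centers["lat2"],
             elevation = stations$elevation - centers["elevation"])
  keep_col <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) sd(v) > 0))
  if (qr(X[, keep_col, drop = FALSE])$rank < sum(keep_col))
    stop("mean-function covariates are collinear across stations",
         call. = FALSE)
  Xf <- X[, keep_col, drop = FALSE]
  p <- ncol(Xf)

  D <- gc_distm_km(cbind(stations$lon, stations$lat))
  dpos <- D[upper.tri(D)]
  dpos <- dpos[dpos > 0]
  if (!length(dpos))
    stop("all stations are co-located; spatial model is unidentifiable",
         call. = FALSE)

  # -2 * restricted log-likelihood at (log range, log nugget/sill ratio),
  # with the sill profiled out analytically.
  neg2reml <- function(par) {
    range_km <- exp(par[1]); lambda <- exp(par[2])
    if (!is.finite(range_km) || !is.finite(lambda)) return(1e12)
    V <- exp(-D / range_km)
    diag(V) <- diag(V) + lambda
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e12)
    Li_X <- backsolve(ch, Xf, transpose = TRUE)
    Li_z <- backsolve(ch, z, transpose = TRUE)
    XtViX <- crossprod(Li_X)
    beta <- tryCatch(solve(XtViX, crossprod(Li_X, Li_z)),
                     error = function(e) NULL)
    if (is.null(beta)) return(1e12)
    r <- Li_z - Li_X %*% beta
    sigma2 <- max(sum(r^2) / (n - p), 1e-12)
    as.numeric((n - p) * log(sigma2) + 2 * sum(log(diag(ch))) +
                 determinant(XtViX, logarithm = TRUE)$modulus +
                 (n - p) * (1 + log(2 * pi)))
  }

  range_starts <- unique(quantile(dpos, seq(0.05, 0.6,
                                            length.out = n_range_starts)))
  lambda_starts <- c(0.01, 0.5, 5)
  best <- NULL
  for (r0 in range_starts) for (l0 in lambda_starts) {
    op <- tryCatch(
      optim(c(log(r0), log(l0)), neg2reml, method = "Nelder-Mead",
            control = control),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e12)
    stop("isoscape fit failure: REML optimizer did not converge ",
         "(n = ", n, " stations)", call. = FALSE)

  # Identifiability guard: when the range collapses below the resolvable
  # scale the sill/nugget split is arbitrary (V ~ (1 + lambda) I for any
  # split). Prefer the pure-nugget model unless the spatial covariance
  # improves the restricted likelihood decisively (chi-square 0.95, 2 df).
  ols_rss <- sum(lm.fit(Xf, z)$residuals^2)
  s2_iid <- ols_rss / (n - p)
  n2_iid <- (n - p) * log(s2_iid) +
    as.numeric(determinant(crossprod(Xf), logarithm = TRUE)$modulus) +
    (n - p) * (1 + log(2 * pi))
  if (n2_iid - best$value < qchisq(0.95, 2)) {
    best$par <- c(log(median(dpos)), log(1e8))
    best$value <- neg2reml(best$par)
  }

  range_km <- exp(best$par[1]); lambda <- exp(best$par[2])
  V <- exp(-D / range_km); diag(V) <- diag(V) + lambda
  ch <- chol(V)
  Li_X <- backsolve(ch, Xf, transpose = TRUE)
  Li_z <- backsolve(ch, z, transpose = TRUE)
  XtViX <- crossprod(Li_X)
  dimnames(XtViX) <- list(colnames(Xf), colnames(Xf))
  XtViX_inv <- solve(XtViX)
  beta <- drop(XtViX_inv %*% crossprod(Li_X, Li_z))
  r <- drop(Li_z - Li_X %*% beta)
  sigma2 <- max(sum(r^2) / (n - p), 1e-12)
  # V^{-1} (z - X beta), needed by the kriging predictor
  vi_resid <- backsolve(ch, r)

  coefs <- setNames(rep(NA_real_, 4),
                    c("(Intercept)", "lat", "lat2", "elevation"))
  coefs[colnames(Xf)] <- beta

  out <- list(
    coefficients = coefs,
    partial_sill = sigma2,
    range_km = range_km,
    nugget = sigma2 * lambda,
    lambda = lambda,
    centers = centers,
    keep_col = keep_col,
    stations = stations,
    X = Xf,
    z = z,
    chol_V = ch,
    vi_resid = vi_resid,
    XtViX_inv = XtViX_inv,
    n = n, p = p,
    neg2reml = best$value,
    vcov = sigma2 * XtViX_inv,
    optim = list(value = best$value, counts = best$counts,
                 convergence = best$convergence)
  )
  class(out) <- "isoscape"
  out
}

# Internal: assemble an isoscape object at fixed covariance parameters
# (GLS mean fit only, no REML search). Used for prediction diagnostics.
iso_with_params <- function(stations, partial_sill, range_km, nugget) {
  n <- nrow(stations)
  z <- parse_permil(stations$mean_d2h)
  centers <- c(lat = mean(stations$lat), lat2 = mean(stations$lat^2),
               elevation = mean(stations$elevation))
  X <- cbind(`(Intercept)` = 1,
             lat = stations$lat - centers["lat"],
             lat2 = stations$lat^2 - centers["lat2"],
             elevation = stations$elevation - centers["elevation"])
  keep_col <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) sd(v) > 0))
  Xf <- X[, keep_col, drop = FALSE]
  lambda <- nugget / partial_sill
  D <- gc_distm_km(cbind(stations$lon, stations$lat))
  V <- exp(-D / range_km); diag(V) <- diag(V) + lambda + 1e-10
  ch <- chol(V)
  Li_X <- backsolve(ch, Xf, transpose = TRUE)
  Li_z <- backsolve(ch, z, transpose = TRUE)
  XtViX <- crossprod(Li_X)
  dimnames(XtViX) <- list(colnames(Xf), colnames(Xf))
  XtViX_inv <- solve(XtViX)
  beta <- drop(XtViX_inv %*% crossprod(Li_X, Li_z))
  r <- drop(Li_z - Li_X %*% beta)
  coefs <- setNames(rep(NA_real_, 4),
                    c("(Intercept)", "lat", "lat2", "elevation"))
  coefs[colnames(Xf)] <- beta
  out <- list(coefficients = coefs, partial_sill = partial_sill,
              range_km = range_km, nugget = nugget, lambda = lambda,
              centers = centers, keep_col = keep_col, stations = stations,
              X = Xf, z = z, chol_V = ch, vi_resid = backsolve(ch, r),
              XtViX_inv = XtViX_inv, n = n, p = ncol(Xf),
              neg2reml = NA_real_, vcov = partial_sill * XtViX_inv,
              optim = NULL)
  class(out) <- "isoscape"
  out
}

# Build the (centered) fixed-effect design for new points.
.iso_design <- function(object, lat, elevation) {
  X0 <- cbind(`(Intercept)` = 1,
              lat = lat - object$centers["lat"],
              lat2 = lat^2 - object$centers["lat2"],
              elevation = elevation - object$centers["elevation"])
  X0[, object$keep_col, drop = FALSE]
}

#' Universal-kriging prediction at arbitrary points
#'
#' Computes the kriging mean and prediction variance of a fitted isoscape at
#' new locations. The prediction target is a new observation, so the
#' variance includes the nugget; at a training station under a zero-nugget
#' model the prediction interpolates the data exactly with zero variance.
#'
#' @param object a fitted \code{"isoscape"}.
#' @param newdata data.frame with columns \code{lon}, \code{lat} and
#'   optionally \code{elevation} (defaults to 0 m: extrapolative when the
#'   elevation coefficient was fitted on stations at altitude).
#' @param ... unused.
#' @return data.frame with columns \code{mean} (per-mil) and \code{var}
#'   (per-mil squared).
#' @export
predict.isoscape <- function(object, newdata, ...) {
  if (missing(newdata)) newdata <- object$stations
  if (!all(c("lon", "lat") %in% names(newdata)))
    stop("newdata needs lon and lat columns", call. = FALSE)
  elev <- if ("elevation" %in% names(newdata)) newdata$elevation else 0
  X0 <- .iso_design(object, newdata$lat, rep(elev, length.out = nrow(newdata)))
  d0 <- gc_distm_km(cbind(newdata$lon, newdata$lat),
                    cbind(object$stations$lon, object$stations$lat))
  c0 <- exp(-d0 / object$range_km)              # m x n correlation
  mu <- drop(X0 %*% object$coefficients[object$keep_col] +
               c0 %*% object$vi_resid)
  # quadratic forms via the cached Cholesky factor
  Li_c0 <- backsolve(object$chol_V, t(c0), transpose = TRUE)  # n x m
  quad1 <- colSums(Li_c0^2)
  U <- t(X0) - crossprod(object$X, backsolve(object$chol_V, Li_c0))
  quad2 <- colSums(U * (object$XtViX_inv %*% U))
  v <- object$partial_sill * pmax((1 + object$lambda) - quad1 + quad2, 0)
  data.frame(mean = mu, var = v)
}

#' Predict an isoscape onto a regular lon/lat grid
#'
#' Evaluates the universal-kriging mean and prediction-variance surfaces on
#' a regular grid of cell centres. Cells are half-open,
#' \code{[west, east) x [south, north)}, and values refer to cell centres.
#'
#' @param model a fitted \code{"isoscape"}.
#' @param bbox numeric \code{c(lon_min, lat_min, lon_max, lat_max)}.
#' @param resolution_deg cell size in decimal degrees (default 0.5).
#' @param elevation elevation (m) assumed for every cell, or a vector/matrix
#'   matching the grid; defaults to 0.
#' @return an object of class \code{"isoscape_grid"}: cell-centre coordinate
#'   vectors \code{lon}, \code{lat} and matrices \code{mean}, \code{var}
#'   (rows = latitudes, south to north).
#' @export
predict_isoscape <- function(model, bbox, resolution_deg = 0.5,
                             elevation = 0) {
  check_bbox(bbox)
  if (resolution_deg <= 0) stop("resolution_deg must be > 0", call. = FALSE)
  n_lon <- ceiling((bbox[3] - bbox[1]) / resolution_deg - 1e-9)
  n_lat <- ceiling((bbox[4] - bbox[2]) / resolution_deg - 1e-9)
  lon <- bbox[1] + (seq_len(n_lon) - 0.5) * resolution_deg
  lat <- bbox[2] + (seq_len(n_lat) - 0.5) * resolution_deg
  cells <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  cells$elevation <- rep(elevation, length.out = nrow(cells))
  pr <- predict(model, cells)
  out <- list(
    bbox = as.numeric(bbox), resolution_deg = resolution_deg,
    lon = lon, lat = lat,
    mean = matrix(pr$mean, nrow = n_lat, ncol = n_lon, byrow = TRUE),
    var = matrix(pr$var, nrow = n_lat, ncol = n_lon, byrow = TRUE),
    model_params = list(
      mean_coefficients = as.list(coef(model)),
      partial_sill = model$partial_sill, range_km = model$range_km,
      nugget = model$nugget)
  )
  class(out) <- "isoscape_grid"
  out
}

#' Look up grid values at points
#'
#' Returns the containing cell's mean and variance for each query point (no
#' interpolation between cells). The half-open cell convention assigns a
#' point lying on a shared edge to the cell on its east/north side.
#'
#' @param grid an \code{"isoscape_grid"}.
#' @param lon,lat numeric vectors of query coordinates.
#' @return data.frame with columns \code{mean} and \code{var} (one row per
#'   query point).
#' @export
isoscape_at <- function(grid, lon, lat) {
  idx <- .grid_index(grid, lon, lat)
  data.frame(mean = grid$mean[idx], var = grid$var[idx])
}

# Row/column index of the half-open cell containing each point; errors when
# any point falls outside the bbox.
.grid_index <- function(grid, lon, lat) {
  b <- grid$bbox; res <- grid$resolution_deg
  out <- lon < b[1] | lon >= b[1] + length(grid$lon) * res |
    lat < b[2] | lat >= b[2] + length(grid$lat) * res
  if (any(out))
    stop("out of domain: ", sum(out), " point(s) outside the grid bbox",
         call. = FALSE)
  i <- floor((lat - b[2]) / res) + 1   # row (latitude)
  j <- floor((lon - b[1]) / res) + 1   # column (longitude)
  cbind(i, j)
}

#' @export
print.isoscape <- function(x, ...) {
  cat("Universal-kriging isoscape (REML)\n")
  cat(sprintf("  stations: %d\n", x$n))
  cat("  mean coefficients:\n")
  print(round(x$coefficients, 5))
  cat(sprintf("  partial sill: %.4g permil^2, range: %.4g km, nugget: %.4g permil^2\n",
              x$partial_sill, x$range_km, x$nugget))
  invisible(x)
}

#' @export
summary.isoscape <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  coefs <- object$coefficients[object$keep_col]
  tab <- cbind(Estimate = coefs, `Std. Error` = se,
               `z value` = coefs / se)
  out <- list(coef_table = tab, partial_sill = object$partial_sill,
              range_km = object$range_km, nugget = object$nugget,
              n = object$n, neg2reml = object$neg2reml)
  class(out) <- "summary.isoscape"
  out
}

#' @export
print.summary.isoscape <- function(x, ...) {
  cat("Universal-kriging isoscape, exponential covariance, REML fit\n\n")
  printCoefmat(x$coef_table)
  cat(sprintf("\npartial sill %.4g permil^2, range %.4g km, nugget %.4g permil^2\n",
              x$partial_sill, x$range_km, x$nugget))
  cat(sprintf("n = %d stations, -2 restricted logLik = %.2f\n",
              x$n, x$neg2reml))
  invisible(x)
}

#' @export
coef.isoscape <- function(object, ...) object$coefficients

#' @export
vcov.isoscape <- function(object, ...) object$vcov

#' @export
fitted.isoscape <- function(object, ...) {
  drop(object$X %*% object$coefficients[object$keep_col])
}

#' @export
residuals.isoscape <- function(object, ...) object$z - fitted(object)

#' @export
logLik.isoscape <- function(object, ...) {
  structure(-object$neg2reml / 2, df = object$p + 3, class = "logLik")
}

#' Simulate new station observations from a fitted isoscape
#'
#' Draws independent realizations of the fitted model (trend + spatially
#' correlated field + nugget) at the training-station locations.
#'
#' @param object a fitted \code{"isoscape"}.
#' @param nsim number of realizations.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with one column per realization.
#' @export
simulate.isoscape <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  D <- gc_distm_km(cbind(object$stations$lon, object$stations$lat))
  S <- object$partial_sill * exp(-D / object$range_km)
  diag(S) <- diag(S) + object$nugget + 1e-8
  L <- chol(S)
  mu <- fitted(object)
  out <- as.data.frame(
    mu + t(L) %*% matrix(rnorm(object$n * nsim), object$n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.isoscape_grid <- function(x, ...) {
  cat(sprintf("Isoscape grid: %d x %d cells at %.3g deg, bbox (%s)\n",
              length(x$lat), length(x$lon), x$resolution_deg,
              paste(x$bbox, collapse = ", ")))
  cat(sprintf("  mean d2h range: [%.1f, %.1f] permil; pred var range: [%.2f, %.2f]\n",
              min(x$mean), max(x$mean), min(x$var), max(x$var)))
  invisible(x)
}

#' @export
as.data.frame.isoscape_grid <- function(x, ...) {
  cells <- expand.grid(lon = x$lon, lat = x$lat, KEEP.OUT.ATTRS = FALSE)
  data.frame(lon = cells$lon, lat = cells$lat,
             mean = as.vector(t(x$mean)), var = as.vector(t(x$var)))
}

#' @export
plot.isoscape_grid <- function(x, what = c("mean", "var"), ...) {
  what <- match.arg(what)
  graphics::image(x$lon, x$lat, t(x[[what]]),
                  xlab = "longitude", ylab = "latitude",
                  main = paste("isoscape", what), ...)
  invisible(x)
}

#' @export
plot.isoscape <- function(x, bbox = NULL, resolution_deg = 0.5, ...) {
  if (is.null(bbox))
    bbox <- c(min(x$stations$lon), min(x$stations$lat),
              max(x$stations$lon) + 1e-6, max(x$stations$lat) + 1e-6)
  g <- predict_isoscape(x, bbox, resolution_deg)
  plot(g, ...)
  graphics::points(x$stations$lon, x$stations$lat, pch = 3)
  invisible(g)
}
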