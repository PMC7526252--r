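# Two-sided normal p-value of observing d2h given expected value yhat and
# total variance v. Vectorized over cells/samples.
.assign_p <- function(d2h, yhat, v) {
  if (any(v <= 0))
    stop("degenerate variance: total assignment variance must be > 0",
         call. = FALSE)
  2 * pnorm(-abs((d2h - yhat) / sqrt(v)))
}

#' Probability-of-origin map for one tissue sample
#'
#' For every grid cell the observed tissue delta-2H is tested against the
#' value expected if the animal had grown the tissue there: expected value
#' \eqn{\hat y(x) = a\,\mu(x) + b} from the transfer function, total variance
#' \eqn{V(x) = a^2 v(x) + \sigma^2_{resid} + \sigma^2_{analytical}} combining
#' isoscape prediction variance, transfer-function residual variance and
#' analytical error. The two-sided normal p-value per cell forms the
#' probability-of-origin map (values in [0, 1]; high p = plausible origin).
#'
#' @param d2h observed tissue delta-2H (per-mil, VSMOW).
#' @param tissue \code{"fur"} or \code{"wing"}; must match \code{tf}.
#' @param tf a \code{"transfer_fn"} for the same tissue.
#' @param grid an \code{"isoscape_grid"}.
#' @param analytical_sd analytical standard deviation (per-mil), default
#'   1.65 (the QC goat-hair SD).
#' @param bat_id optional identifier carried through to outputs.
#' @return object of class \code{"assignment_map"}: grid geometry plus a
#'   matrix \code{p} of per-cell p-values.
#' @export
assign_sample <- function(d2h, tissue = c("fur", "wing"), tf, grid,
                          analytical_sd = 1.65, bat_id = NULL) {
  tissue <- match.arg(tissue)
  if (!inherits(tf, "transfer_fn") || tf$tissue != tissue)
    stop("tissue mismatch: transfer function is for '", tf$tissue,
         "', sample is '", tissue, "'", call. = FALSE)
  d2h <- parse_permil(d2h)
  if (length(d2h) != 1 || !is.finite(d2h))
    stop("d2h must be a single finite value", call. = FALSE)
  yhat <- tf$slope * grid$mean + tf$intercept
  v <- tf$slope^2 * grid$var + tf$resid_var + analytical_sd^2
  out <- list(
    bat_id = bat_id, tissue = tissue, d2h = d2h,
    bbox = grid$bbox, resolution_deg = grid$resolution_deg,
    lon = grid$lon, lat = grid$lat,
    p = .assign_p(d2h, yhat, v)
  )
  class(out) <- "assignment_map"
  out
}

#' @export
print.assignment_map <- function(x, ...) {
  cat(sprintf("Assignment map%s (%s, d2h = %.2f permil): %d x %d cells\n",
              if (is.null(x$bat_id)) "" else paste0(" for ", x$bat_id),
              x$tissue, x$d2h, length(x$lat), length(x$lon)))
  cat(sprintf("  p range [%.3g, %.3g]; %.1f%% of cells with p >= 0.05\n",
              min(x$p), max(x$p), 100 * mean(x$p >= 0.05)))
  invisible(x)
}

#' @export
plot.assignment_map <- function(x, site = NULL, ...) {
  graphics::image(x$lon, x$lat, t(x$p), zlim = c(0, 1),
                  xlab = "longitude", ylab = "latitude",
                  main = paste("p of origin:",
                               if (is.null(x$bat_id)) x$tissue
                               else paste(x$bat_id, x$tissue)), ...)
  if (!is.null(site)) graphics::points(site[1], site[2], pch = 4, cex = 2)
  invisible(x)
}

#' @export
as.data.frame.assignment_map <- function(x, ...) {
  cells <- expand.grid(lon = x$lon, lat = x$lat, KEEP.OUT.ATTRS = FALSE)
  data.frame(lon = cells$lon, lat = cells$lat, p = as.vector(t(x$p)))
}

#' Local / non-local call at the sampling site
#'
#' Reads the p-value of the cell containing the sampling site off an
#' assignment map and rejects the site as the sample's origin when
#' p < alpha (strict, so boundary cases are conservatively called local).
#'
#' @param map an \code{"assignment_map"}.
#' @param site numeric \code{c(lon, lat)} of the sampling site.
#' @param alpha significance level, default 0.05.
#' @return list of class \code{"locality_call"}: \code{bat_id},
#'   \code{tissue}, \code{p_at_site}, \code{alpha}, \code{call}
#'   (\code{"local"} or \code{"non-local"}).
#' @export
call_locality <- function(map, site, alpha = 0.05) {
  idx <- .grid_index(map, site[1], site[2])
  p_at_site <- map$p[idx]
  out <- list(bat_id = map$bat_id, tissue = map$tissue,
              p_at_site = p_at_site, alpha = alpha,
              call = if (p_at_site < alpha) "non-local" else "local")
  class(out) <- "locality_call"
  out
}

#' @export
print.locality_call <- function(x, ...) {
  cat(sprintf("%s %s: p at site = %.4g (alpha = %g) -> %s\n",
              if (is.null(x$bat_id)) "sample" else x$bat_id,
              x$tissue, x$p_at_site, x$alpha, x$call))
  invisible(x)
}

#' Combined (group) assignment map via Fisher's method
#'
#' Combines the per-cell p-values of several assignment maps into one map:
#' \eqn{X = -2\sum_i \log p_i} referred to the upper tail of a chi-square
#' distribution with \eqn{2k} degrees of freedom. Input p-values are floored
#' at 1e-300 before taking logs.
#'
#' @param maps list of \code{"assignment_map"} objects sharing grid geometry.
#' @return an \code{"assignment_map"} whose \code{p} is the combined map.
#' @export
group_assignment <- function(maps) {
  if (!length(maps)) stop("empty map list", call. = FALSE)
  g0 <- maps[[1]]
  for (m in maps) {
    if (!inherits(m, "assignment_map"))
      stop("all elements must be assignment maps", call. = FALSE)
    if (!identical(dim(m$p), dim(g0$p)) ||
        !isTRUE(all.equal(m$bbox, g0$bbox)) ||
        !isTRUE(all.equal(m$resolution_deg, g0$resolution_deg)))
      stop("geometry mismatch between assignment maps", call. = FALSE)
  }
  k <- length(maps)
  X <- Reduce(`+`, lapply(maps, function(m) -2 * log(pmax(m$p, 1e-300))))
  out <- g0
  out$bat_id <- paste0("group_of_", k)
  out$d2h <- NA_real_
  out$p <- matrix(pchisq(X, df = 2 * k, lower.tail = FALSE),
                  nrow = nrow(g0$p), ncol = ncol(g0$p))
  out
}

#' Local / non-local calls for every tissue sample in a bat table
#'
#' Vectorized pipeline stage: for each row of a long-format bat table,
#' computes the assignment p-value at the sampling site (without building
#' full maps) and calls the sample local or non-local.
#'
#' @param bats long-format bat table.
#' @param tfs named list of transfer functions, \code{list(fur = ..., wing
#'   = ...)}; tissues without a transfer function are skipped.
#' @param grid an \code{"isoscape_grid"} covering all sites.
#' @param analytical_sd analytical SD (per-mil), default 1.65.
#' @param alpha significance level, default 0.05.
#' @return data.frame with columns \code{bat_id}, \code{site_id},
#'   \code{season}, \code{sex}, \code{tissue}, \code{p_at_site},
#'   \code{alpha}, \code{call}.
#' @export
locality_calls <- function(bats, tfs, grid, analytical_sd = 1.65,
                           alpha = 0.05) {
  bats <- .check_bats(bats)
  bats <- bats[bats$tissue %in% names(tfs), , drop = FALSE]
  iso <- isoscape_at(grid, bats$lon, bats$lat)
  slope <- vapply(tfs, `[[`, numeric(1), "slope")[bats$tissue]
  intercept <- vapply(tfs, `[[`, numeric(1), "intercept")[bats$tissue]
  resid_var <- vapply(tfs, `[[`, numeric(1), "resid_var")[bats$tissue]
  yhat <- slope * iso$mean + intercept
  v <- slope^2 * iso$var + resid_var + analytical_sd^2
  p <- .assign_p(bats$d2h, yhat, v)
  data.frame(
    bat_id = bats$bat_id, site_id = bats$site_id, season = bats$season,
    sex = bats$sex, tissue = bats$tissue, p_at_site = p, alpha = alpha,
    call = ifelse(p < alpha, "non-local", "local"),
    stringsAsFactors = FALSE
  )
}
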