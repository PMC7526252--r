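# Long-format bat tables: one row per tissue sample with columns
# bat_id, site_id, lon, lat, season, sex, tissue, d2h.

.check_bats <- function(bats) {
  need <- c("bat_id", "site_id", "lon", "lat", "season", "sex", "tissue",
            "d2h")
  miss <- setdiff(need, names(bats))
  if (length(miss))
    stop("bats table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(bats$tissue), c("fur", "wing"))
  if (length(bad))
    stop("unknown tissue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dup <- duplicated(bats[, c("bat_id", "tissue")])
  if (any(dup))
    stop("duplicate (bat_id, tissue) rows: ",
         paste(unique(bats$bat_id[dup]), collapse = ", "), call. = FALSE)
  bats$d2h <- parse_permil(bats$d2h)
  if (any(!is.finite(bats$d2h)))
    stop("non-finite d2h in bats table", call. = FALSE)
  bats
}

# Wide per-bat view: one row per bat with fur_d2h / wing_d2h columns.
.bats_wide <- function(bats) {
  bats <- .check_bats(bats)
  first <- bats[!duplicated(bats$bat_id),
                c("bat_id", "site_id", "lon", "lat", "season", "sex")]
  fur <- bats[bats$tissue == "fur", c("bat_id", "d2h")]
  wing <- bats[bats$tissue == "wing", c("bat_id", "d2h")]
  names(fur)[2] <- "fur_d2h"; names(wing)[2] <- "wing_d2h"
  out <- merge(merge(first, fur, by = "bat_id", all.x = TRUE),
               wing, by = "bat_id", all.x = TRUE, sort = FALSE)
  out[match(first$bat_id, out$bat_id), ]
}

#' Fur-wing delta-2H difference per bat
#'
#' Computes \eqn{\Delta\delta^2H = |\delta^2H_{wing} - \delta^2H_{fur}|}
#' for every bat carrying both tissues. Small values indicate both tissues
#' grew in isotopically similar places and are the working proxy for
#' sedentariness.
#'
#' @param bats long-format bat table (one row per tissue sample).
#' @param require_both error if any bat lacks one of the two tissues
#'   (default \code{FALSE}: such bats are dropped).
#' @return data.frame with columns \code{bat_id} and \code{delta_d2h}.
#' @export
delta_diff <- function(bats, require_both = FALSE) {
  w <- .bats_wide(bats)
  incomplete <- is.na(w$fur_d2h) | is.na(w$wing_d2h)
  if (require_both && any(incomplete))
    stop("incomplete record(s), missing a tissue: ",
         paste(utils::head(w$bat_id[incomplete], 5), collapse = ", "),
         call. = FALSE)
  w <- w[!incomplete, , drop = FALSE]
  data.frame(bat_id = w$bat_id,
             delta_d2h = abs(w$wing_d2h - w$fur_d2h),
             stringsAsFactors = FALSE)
}

#' Select putatively sedentary calibration animals
#'
#' In the absence of a known-sedentary reference species, bats whose fur and
#' wing delta-2H agree to better than the analytical precision of the QC
#' standard are assumed sedentary and used to calibrate the tissue transfer
#' functions. Selection is strict: \eqn{\Delta\delta^2H <} threshold.
#'
#' @param bats long-format bat table.
#' @param threshold per-mil agreement threshold; defaults to 1.65, the QC
#'   (goat hair) standard deviation.
#' @return the rows of \code{bats} belonging to selected bats, input order
#'   preserved.
#' @export
select_calibrators <- function(bats, threshold = 1.65) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  dd <- delta_diff(bats)
  keep_ids <- dd$bat_id[dd$delta_d2h < threshold]
  if (!length(keep_ids))
    stop("empty calibration set: no dual-tissue bat has delta-d2H < ",
         threshold, " permil", call. = FALSE)
  bats[bats$bat_id %in% keep_ids, , drop = FALSE]
}

#' Fit a tissue transfer function on calibration animals
#'
#' Ordinary least squares of tissue delta-2H on the isoscape's kriged mean
#' at each calibrator's sampling site, one fit per tissue, both seasons
#' pooled. The residual variance (RSS divided by n - 2) re-enters the
#' assignment test's total variance.
#'
#' @param calibrators long-format bat table of selected calibrators (see
#'   [select_calibrators()]).
#' @param tissue \code{"fur"} or \code{"wing"}.
#' @param grid an \code{"isoscape_grid"} covering all calibrator sites.
#' @return object of class \code{"transfer_fn"}: \code{tissue},
#'   \code{slope}, \code{intercept}, \code{resid_var}, \code{n_calibrators},
#'   \code{df}.
#' @export
fit_transfer <- function(calibrators, tissue = c("fur", "wing"), grid) {
  tissue <- match.arg(tissue)
  cal <- .check_bats(calibrators)
  cal <- cal[cal$tissue == tissue, , drop = FALSE]
  if (nrow(cal) < 3)
    stop("insufficient calibrators for tissue '", tissue, "': need >= 3, got ",
         nrow(cal), call. = FALSE)
  iso <- isoscape_at(grid, cal$lon, cal$lat)$mean
  if (sd(iso) == 0)
    stop("degenerate design: isoscape means identical at all calibrator sites",
         call. = FALSE)
  fit <- lm(cal$d2h ~ iso)
  rss <- sum(residuals(fit)^2)
  n <- nrow(cal)
  s2 <- rss / fit$df.residual
  sxx <- sum((iso - mean(iso))^2)
  out <- list(
    tissue = tissue,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    resid_var = s2,
    n_calibrators = n,
    df = fit$df.residual,
    slope_se = sqrt(s2 / sxx),
    intercept_se = sqrt(s2 * (1 / n + mean(iso)^2 / sxx))
  )
  class(out) <- "transfer_fn"
  out
}

#' @export
print.transfer_fn <- function(x, ...) {
  cat(sprintf("Transfer function (%s): d2h_%s = %.4g * d2h_isoscape + %.4g\n",
              x$tissue, x$tissue, x$slope, x$intercept))
  cat(sprintf("  residual variance %.4g permil^2 on %d df (n = %d calibrators)\n",
              x$resid_var, x$df, x$n_calibrators))
  invisible(x)
}

#' @export
coef.transfer_fn <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Expected tissue value under a transfer function
#'
#' @param object a \code{"transfer_fn"}.
#' @param iso_d2h numeric vector of isoscape delta-2H values (per-mil).
#' @param ... unused.
#' @return numeric vector of expected tissue delta-2H.
#' @export
predict.transfer_fn <- function(object, iso_d2h, ...) {
  object$slope * iso_d2h + object$intercept
}
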