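#' Keratin reference materials for two-point normalization
#'
#' Accepted non-exchangeable hydrogen isotope values (per-mil vs VSMOW) of
#' the USGS42 and USGS43 human-hair reference materials, the standard pair
#' for matrix-matched (comparative equilibration) normalization of keratin
#' samples.
#'
#' @return a data.frame with columns \code{name}, \code{accepted_d2h},
#'   \code{accepted_sd}.
#' @export
usgs_hair_refs <- function() {
  data.frame(
    name = c("USGS42", "USGS43"),
    accepted_d2h = c(-72.2, -44.2),
    accepted_sd = c(0.9, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Fit a two-point (or least-squares) normalization line for one run
#'
#' Regresses the accepted reference values on the measured values so raw
#' instrument-scale delta-2H can be mapped to the VSMOW scale of
#' non-exchangeable hydrogen. Replicate measurements of the same reference
#' material within a run are averaged before fitting. With exactly two
#' reference materials the line passes through both accepted values exactly;
#' with more, ordinary least squares is used.
#'
#' @param measured numeric vector of measured raw delta-2H for reference
#'   materials (per-mil, instrument scale).
#' @param refs data.frame with columns \code{name} and \code{accepted_d2h}
#'   (see [usgs_hair_refs()]).
#' @param names character vector parallel to \code{measured} naming the
#'   reference material of each measurement.
#' @param run_id optional run identifier used in error messages.
#' @return a list with elements \code{slope}, \code{intercept},
#'   \code{n_refs}, of class \code{"d2h_norm"}.
#' @export
fit_normalization <- function(measured, refs, names, run_id = NULL) {
  run_lab <- if (is.null(run_id)) "" else paste0(" in run '", run_id, "'")
  if (length(measured) != length(names))
    stop("measured and names must have the same length", call. = FALSE)
  if (anyNA(measured) || any(!is.finite(measured)))
    stop("non-finite reference measurement", run_lab, call. = FALSE)
  keep <- names %in% refs$name
  measured <- measured[keep]
  names <- names[keep]
  mean_meas <- tapply(measured, names, mean)
  accepted <- refs$accepted_d2h[match(base::names(mean_meas), refs$name)]
  distinct <- !duplicated(accepted)
  if (sum(distinct) < 2)
    stop("normalization impossible", run_lab,
         ": need >= 2 reference materials with distinct accepted values",
         call. = FALSE)
  if (length(unique(round(mean_meas, 12))) < 2)
    stop("degenerate run", run_lab,
         ": distinct reference materials measured at identical values",
         call. = FALSE)
  fit <- lm(accepted ~ mean_meas)
  out <- list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n_refs = length(mean_meas),
    run_id = run_id
  )
  class(out) <- "d2h_norm"
  out
}

#' @export
print.d2h_norm <- function(x, ...) {
  cat(sprintf("Two-point delta-2H normalization (%d reference materials)\n",
              x$n_refs))
  cat(sprintf("  accepted = %.6g * measured + %.6g\n", x$slope, x$intercept))
  invisible(x)
}

#' Normalize the raw measurements of one or more analytical runs
#'
#' Applies [fit_normalization()] per run and maps every measurement (samples,
#' references and QC standards alike) onto the VSMOW non-exchangeable
#' hydrogen scale. Reference and QC records keep their normalized values so
#' analytical precision can be assessed downstream.
#'
#' @param run data.frame with columns \code{run_id}, \code{sample_id},
#'   \code{role} (one of \code{"sample"}, \code{"reference"}, \code{"qc"})
#'   and \code{raw_d2h}. Reference rows are matched to \code{refs} via
#'   \code{sample_id}.
#' @param refs reference-material table (see [usgs_hair_refs()]).
#' @return data.frame with columns \code{sample_id}, \code{d2h},
#'   \code{run_id}, \code{role}.
#' @export
normalize_run <- function(run, refs) {
  need <- c("run_id", "sample_id", "role", "raw_d2h")
  miss <- setdiff(need, names(run))
  if (length(miss))
    stop("runs table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_role <- setdiff(unique(run$role), c("sample", "reference", "qc"))
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  run$raw_d2h <- parse_permil(run$raw_d2h)
  if (any(!is.finite(run$raw_d2h)))
    stop("non-finite raw_d2h values present", call. = FALSE)
  pieces <- lapply(split(run, run$run_id), function(rr) {
    ref_rows <- rr[rr$role == "reference", , drop = FALSE]
    nm <- fit_normalization(ref_rows$raw_d2h, refs, ref_rows$sample_id,
                            run_id = rr$run_id[1])
    data.frame(
      sample_id = rr$sample_id,
      d2h = nm$slope * rr$raw_d2h + nm$intercept,
      run_id = rr$run_id,
      role = rr$role,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Analytical precision from repeated QC standards
#'
#' Sample standard deviation (n - 1 denominator) of a quality-control
#' standard measured repeatedly across runs, after per-run normalization.
#' The resulting SD is the default analytical uncertainty and the default
#' threshold for selecting putatively sedentary calibration animals.
#'
#' @param qc_values numeric vector of normalized QC delta-2H values.
#' @param name QC material name (e.g. \code{"goat hair"}).
#' @return list with \code{qc_name}, \code{sd}, \code{n}, of class
#'   \code{"qc_precision"}.
#' @export
qc_precision <- function(qc_values, name = "qc") {
  qc_values <- qc_values[is.finite(qc_values)]
  if (length(qc_values) < 2)
    stop("insufficient replicates: need >= 2 QC values for '", name, "'",
         call. = FALSE)
  out <- list(qc_name = name, sd = sd(qc_values), n = length(qc_values))
  class(out) <- "qc_precision"
  out
}

#' @export
print.qc_precision <- function(x, ...) {
  cat(sprintf("QC '%s': SD = %.3f permil (n = %d)\n", x$qc_name, x$sd, x$n))
  invisible(x)
}
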