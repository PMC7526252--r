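#' Summer station means from monthly precipitation records
#'
#' Filters GNIP-style monthly precipitation delta-2H records to a year range
#' and month set (June-August by default) and aggregates them to one summary
#' row per station. When every retained record of a station carries a
#' precipitation amount, the mean is amount-weighted (the GNIP convention);
#' otherwise the unweighted arithmetic mean is used.
#'
#' @param records data.frame with columns \code{station_id}, \code{lon},
#'   \code{lat}, \code{elevation}, \code{year}, \code{month}, \code{d2h} and
#'   optionally \code{precip_mm}.
#' @param years inclusive year range, \code{c(first, last)}.
#' @param months integer vector of calendar months to keep.
#' @param weighted use precipitation-amount weighting when amounts are
#'   available (default \code{TRUE}).
#' @return data.frame with one row per station: \code{station_id},
#'   \code{lon}, \code{lat}, \code{elevation}, \code{mean_d2h},
#'   \code{n_months}, \code{total_precip_mm} (NA when unweighted).
#' @export
summarize_stations <- function(records, years = c(2005, 2017),
                               months = 6:8, weighted = TRUE) {
  need <- c("station_id", "lon", "lat", "elevation", "year", "month", "d2h")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("station table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"precip_mm" %in% names(records)) records$precip_mm <- NA_real_
  records$d2h <- parse_permil(records$d2h)
  keep <- records$year >= years[1] & records$year <= years[2] &
    records$month %in% months
  dropped <- setdiff(unique(records$station_id),
                     unique(records$station_id[keep]))
  if (length(dropped) == length(unique(records$station_id)))
    stop("empty stations: no records survive the year/month filter for ",
         "station(s) ", paste(utils::head(dropped, 5), collapse = ", "),
         call. = FALSE)
  recs <- records[keep, , drop = FALSE]
  pieces <- lapply(split(recs, recs$station_id), function(s) {
    if (any(s$lon != s$lon[1]) || any(s$lat != s$lat[1]))
      stop("station '", s$station_id[1], "' has inconsistent coordinates",
           call. = FALSE)
    w_ok <- weighted && all(is.finite(s$precip_mm)) && sum(s$precip_mm) > 0
    mean_d2h <- if (w_ok) sum(s$precip_mm * s$d2h) / sum(s$precip_mm)
                else mean(s$d2h)
    data.frame(
      station_id = s$station_id[1], lon = s$lon[1], lat = s$lat[1],
      elevation = s$elevation[1], mean_d2h = mean_d2h,
      n_months = nrow(s),
      total_precip_mm = if (w_ok) sum(s$precip_mm) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
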