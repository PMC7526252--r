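#' @import stats
#' @importFrom utils read.csv write.csv
NULL

# Authalic sphere radius (km) used for all great-circle geometry.
.EARTH_RADIUS_KM <- 6371.0072

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0072 km between two sets of
#' points given as decimal-degree longitude/latitude.
#'
#' @param p1,p2 two-column matrices (lon, lat) or length-2 vectors.
#' @return numeric vector of distances in kilometres.
#' @export
gc_dist_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = .EARTH_RADIUS_KM * 1000) / 1000
}

# Full pairwise distance matrix (km) between rows of lon/lat matrices.
gc_distm_km <- function(x, y = x) {
  geosphere::distm(x, y, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = .EARTH_RADIUS_KM * 1000)
  }) / 1000
}

# Destination point: start lon/lat, initial bearing (degrees), distance (km),
# on the same sphere as gc_dist_km.
dest_point <- function(lon, lat, bearing_deg, dist_km) {
  geosphere::destPoint(cbind(lon, lat), bearing_deg, dist_km * 1000,
                       a = .EARTH_RADIUS_KM * 1000, f = 0)
}

#' Parse per-mil values written with typographic minus signs
#'
#' Published tables often typeset negative per-mil values as, e.g.,
#' \dQuote{\eqn{- 20.37}} with a Unicode minus and a space. This helper
#' converts such strings (or plain numerics) to numeric, tolerating both the
#' Unicode minus (U+2212) and whitespace between the sign and the digits.
#'
#' @param x character or numeric vector.
#' @return numeric vector.
#' @examples
#' parse_permil(c("-20.37", "− 20.37", " -14.8 "))
#' @export
parse_permil <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- gsub("−", "-", as.character(x))
  x <- gsub("-\\s+", "-", trimws(x))
  as.numeric(x)
}

# Validate a bbox c(lon_min, lat_min, lon_max, lat_max).
check_bbox <- function(bbox) {
  if (length(bbox) != 4 || anyNA(bbox))
    stop("bbox must be c(lon_min, lat_min, lon_max, lat_max)", call. = FALSE)
  if (bbox[1] >= bbox[3] || bbox[2] >= bbox[4])
    stop("degenerate bbox: min edges must be strictly below max edges",
         call. = FALSE)
  if (bbox[1] < -180 || bbox[3] > 180 || bbox[2] < -90 || bbox[4] > 90)
    stop("invalid bbox: outside plausible lon/lat ranges", call. = FALSE)
  invisible(bbox)
}
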