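#' Configuration for a synthetic isotope world
#'
#' Bundles every knob of the synthetic-data generator: the deterministic
#' delta-2H surface (base level, latitudinal gradient, elevation gradient),
#' the spatially correlated field on top of it, the station network, the
#' bat colonies with their migrant fraction and displacement distribution,
#' the true tissue transfer functions, and the analytical noise.
#'
#' Defaults describe a southern-European summer precipitation scenario:
#' delta-2H falling ~2 per-mil per degree of latitude northwards across a
#' (-12, 34) to (30, 48) window, a correlated field with 4 per-mil SD and
#' 300 km range, colonies of mostly sedentary bats with a quarter of
#' migrants displaced 250-1000 km, and tissue values produced by the
#' fur/wing transfer lines with 3 per-mil residual SD plus 1.65 per-mil
#' analytical SD.
#'
#' @param seed integer RNG seed.
#' @param bbox study window \code{c(lon_min, lat_min, lon_max, lat_max)}.
#' @param n_stations number of precipitation stations.
#' @param surface list: \code{base} (per-mil), \code{lat_gradient}
#'   (per-mil/degree), \code{elevation_gradient} (per-mil/m).
#' @param field list: \code{partial_sill} (per-mil^2), \code{range_km},
#'   \code{nugget} (per-mil^2) of the Gaussian random field and
#'   station-level noise.
#' @param n_sites,bats_per_site colony layout.
#' @param migrant_fraction probability a bat is a migrant.
#' @param displacement_km either a single distance or \code{c(min, max)}
#'   for a uniform draw.
#' @param displacement_bearing \code{NULL} for a uniform random bearing, or
#'   a vector of candidate bearings in degrees (0 = north) sampled
#'   uniformly; e.g. \code{c(0, 180)} displaces along the latitudinal
#'   gradient in whichever direction stays inside the bbox.
#' @param transfer_truth per-tissue true transfer parameters,
#'   \code{list(fur = c(slope, intercept, resid_sd), wing = ...)}.
#' @param analytical_sd per-mil analytical SD added to tissue values.
#' @param wing_fraction fraction of bats with a wing biopsy in addition to
#'   fur (default 0.62, the typical wing-to-fur sampling ratio of field
#'   campaigns where biopsies are taken from a subset of captures).
#' @param recent_arrival_fraction fraction of migrants whose wing (a fast
#'   regenerating tissue) already reflects the capture site rather than the
#'   origin, producing fur/wing disagreement.
#' @param years,months year range and month set of the generated station
#'   records.
#' @return list of class \code{"synth_config"}.
#' @export
synth_config <- function(seed = 1,
                         bbox = c(-12, 34, 30, 48),
                         n_stations = 150,
                         surface = list(base = 38, lat_gradient = -2,
                                        elevation_gradient = -0.015),
                         field = list(partial_sill = 16, range_km = 300,
                                      nugget = 4),
                         n_sites = 10,
                         bats_per_site = 20,
                         migrant_fraction = 0.25,
                         displacement_km = c(250, 1000),
                         displacement_bearing = NULL,
                         transfer_truth = list(
                           fur = c(slope = 0.62, intercept = -14.66,
                                   resid_sd = 3),
                           wing = c(slope = 0.64, intercept = -14.64,
                                    resid_sd = 3)),
                         analytical_sd = 1.65,
                         wing_fraction = 0.62,
                         recent_arrival_fraction = 0.25,
                         years = c(2005, 2017),
                         months = 6:8) {
  cfg <- list(seed = seed, bbox = check_bbox(bbox), n_stations = n_stations,
              surface = surface, field = field, n_sites = n_sites,
              bats_per_site = bats_per_site,
              migrant_fraction = migrant_fraction,
              displacement_km = displacement_km,
              displacement_bearing = displacement_bearing,
              transfer_truth = transfer_truth,
              analytical_sd = analytical_sd,
              wing_fraction = wing_fraction,
              recent_arrival_fraction = recent_arrival_fraction,
              years = years, months = months)
  stopifnot(cfg$field$partial_sill >= 0, cfg$field$nugget >= 0,
            cfg$field$range_km > 0, cfg$analytical_sd >= 0,
            cfg$migrant_fraction >= 0, cfg$migrant_fraction <= 1,
            cfg$wing_fraction >= 0, cfg$wing_fraction <= 1)
  class(cfg) <- "synth_config"
  cfg
}

# One joint Gaussian-random-field draw at the supplied points (Cholesky on
# the full covariance so stations and bat origins see the same surface).
.grf_draw <- function(lonlat, partial_sill, range_km) {
  n <- nrow(lonlat)
  if (partial_sill <= 0) return(numeric(n))
  D <- gc_distm_km(lonlat)
  S <- partial_sill * exp(-D / range_km)
  diag(S) <- diag(S) + 1e-8 * partial_sill
  drop(t(chol(S)) %*% rnorm(n))
}

#' Generate a complete synthetic world with known ground truth
#'
#' Draws a smooth continental delta-2H surface plus a spatially correlated
#' field, samples a station network from it (monthly records with
#' station-level noise, within-summer variation and precipitation amounts),
#' places bat colonies, displaces a migrant fraction by known great-circle
#' distances, and generates fur and wing delta-2H through the configured
#' transfer functions. Fur reflects the true (summer) origin; for a
#' configurable fraction of migrants the wing, a fast-regenerating tissue,
#' already reflects the capture site.
#'
#' @param config a [synth_config()].
#' @return list with \code{stations} (monthly records), \code{bats}
#'   (long-format tissue table), \code{truth} (per-bat origin, migrant flag
#'   and displacement), \code{surface_at} (function: lon, lat, elevation ->
#'   true surface value at generated points) and \code{config}.
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  b <- config$bbox
  sf <- config$surface
  fl <- config$field

  # station network
  st <- data.frame(
    station_id = sprintf("ST%03d", seq_len(config$n_stations)),
    lon = runif(config$n_stations, b[1], b[3]),
    lat = runif(config$n_stations, b[2], b[4]),
    elevation = pmin(rexp(config$n_stations, 1 / 300), 2500)
  )

  # colonies (kept off the bbox edge so displaced origins can stay inside)
  margin <- 0.05 * c(b[3] - b[1], b[4] - b[2])
  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(config$n_sites)),
    lon = runif(config$n_sites, b[1] + margin[1], b[3] - margin[1]),
    lat = runif(config$n_sites, b[2] + margin[2], b[4] - margin[2])
  )

  # bats and their true origins
  n_bats <- config$n_sites * config$bats_per_site
  bat <- data.frame(
    bat_id = sprintf("B%04d", seq_len(n_bats)),
    site_id = rep(sites$site_id, each = config$bats_per_site)
  )
  bat$site_lon <- sites$lon[match(bat$site_id, sites$site_id)]
  bat$site_lat <- sites$lat[match(bat$site_id, sites$site_id)]
  bat$season <- sample(c("spring", "autumn"), n_bats, replace = TRUE)
  bat$sex <- sample(c("male", "female"), n_bats, replace = TRUE)
  bat$is_migrant <- runif(n_bats) < config$migrant_fraction
  disp <- config$displacement_km
  bat$displacement_km <- ifelse(
    bat$is_migrant,
    if (length(disp) == 2) runif(n_bats, disp[1], disp[2])
    else rep(disp, n_bats),
    0)

  bat$origin_lon <- bat$site_lon
  bat$origin_lat <- bat$site_lat
  for (i in which(bat$is_migrant)) {
    ok <- FALSE
    for (try in seq_len(100)) {
      bearing <- if (is.null(config$displacement_bearing))
        runif(1, 0, 360)
      else config$displacement_bearing[
        sample.int(length(config$displacement_bearing), 1)]
      dst <- dest_point(bat$site_lon[i], bat$site_lat[i], bearing,
                        bat$displacement_km[i])
      if (dst[1] >= b[1] && dst[1] < b[3] && dst[2] >= b[2] &&
          dst[2] < b[4]) {
        bat$origin_lon[i] <- dst[1]; bat$origin_lat[i] <- dst[2]
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("config error: displacement of ",
           round(bat$displacement_km[i]), " km cannot stay inside the bbox ",
           "after 100 bearing retries", call. = FALSE)
  }

  # wing origin: capture site for sedentary bats and recent-arrival migrants
  recent <- bat$is_migrant & runif(n_bats) < config$recent_arrival_fraction
  bat$wing_origin_lon <- ifelse(recent, bat$site_lon, bat$origin_lon)
  bat$wing_origin_lat <- ifelse(recent, bat$site_lat, bat$origin_lat)

  # joint GRF over stations, sites, fur origins and wing origins so the
  # truth surface is consistent everywhere it is evaluated
  pts <- rbind(cbind(st$lon, st$lat),
               cbind(bat$origin_lon, bat$origin_lat),
               cbind(bat$wing_origin_lon, bat$wing_origin_lat))
  uniq <- !duplicated(round(pts, 10))
  upts <- pts[uniq, , drop = FALSE]
  g <- .grf_draw(upts, fl$partial_sill, fl$range_km)
  ukeys <- paste(round(upts[, 1], 10), round(upts[, 2], 10))
  grf_at <- function(lon, lat) {
    g[match(paste(round(lon, 10), round(lat, 10)), ukeys)]
  }
  surface_at <- function(lon, lat, elevation = 0) {
    sf$base + sf$lat_gradient * lat + sf$elevation_gradient * elevation +
      grf_at(lon, lat)
  }

  # monthly station records: station-level noise (the nugget) plus small
  # within-summer month-to-month variation and lognormal rain amounts
  s_station <- surface_at(st$lon, st$lat, st$elevation) +
    rnorm(config$n_stations, 0, sqrt(fl$nugget))
  ym <- expand.grid(year = seq(config$years[1], config$years[2]),
                    month = config$months, KEEP.OUT.ATTRS = FALSE)
  recs <- do.call(rbind, lapply(seq_len(config$n_stations), function(i) {
    keep <- runif(nrow(ym)) < 0.8   # incomplete records, as in real networks
    if (!any(keep)) keep[1] <- TRUE
    data.frame(
      station_id = st$station_id[i], lon = st$lon[i], lat = st$lat[i],
      elevation = st$elevation[i],
      year = ym$year[keep], month = ym$month[keep],
      d2h = s_station[i] + rnorm(sum(keep), 0, 2),
      precip_mm = rlnorm(sum(keep), log(40), 0.6)
    )
  }))
  rownames(recs) <- NULL

  # tissue values through the true transfer functions
  tt <- config$transfer_truth
  tis_noise <- function(sd) sqrt(sd^2 + config$analytical_sd^2)
  fur_d2h <- unname(tt$fur["slope"] *
    surface_at(bat$origin_lon, bat$origin_lat) + tt$fur["intercept"] +
    rnorm(n_bats, 0, tis_noise(tt$fur["resid_sd"])))
  wing_d2h <- unname(tt$wing["slope"] *
    surface_at(bat$wing_origin_lon, bat$wing_origin_lat) +
    tt$wing["intercept"] +
    rnorm(n_bats, 0, tis_noise(tt$wing["resid_sd"])))
  has_wing <- runif(n_bats) < config$wing_fraction

  base_cols <- data.frame(
    bat_id = bat$bat_id, site_id = bat$site_id,
    lon = bat$site_lon, lat = bat$site_lat,
    season = bat$season, sex = bat$sex, stringsAsFactors = FALSE)
  bats_long <- rbind(
    cbind(base_cols, tissue = "fur", d2h = fur_d2h),
    cbind(base_cols[has_wing, ], tissue = "wing", d2h = wing_d2h[has_wing]))
  bats_long <- bats_long[order(bats_long$bat_id, bats_long$tissue), ]
  rownames(bats_long) <- NULL

  truth <- data.frame(
    bat_id = bat$bat_id, site_id = bat$site_id,
    origin_lon = bat$origin_lon, origin_lat = bat$origin_lat,
    wing_origin_lon = bat$wing_origin_lon,
    wing_origin_lat = bat$wing_origin_lat,
    is_migrant = bat$is_migrant,
    displacement_km = gc_dist_km(cbind(bat$site_lon, bat$site_lat),
                                 cbind(bat$origin_lon, bat$origin_lat)),
    stringsAsFactors = FALSE)

  list(stations = recs, bats = bats_long, truth = truth,
       surface_at = surface_at, sites = sites, config = config)
}

#' Score pipeline classifications against synthetic ground truth
#'
#' @param classifications output of [combine_tissues()].
#' @param truth the \code{truth} table of [make_world()].
#' @return list with \code{confusion} (2 x 2 table, truth x call),
#'   \code{sensitivity} (migrants called non-local) and \code{specificity}
#'   (sedentary bats called local).
#' @export
score_pipeline <- function(classifications, truth) {
  m <- merge(classifications[, c("bat_id", "combined")],
             truth[, c("bat_id", "is_migrant")], by = "bat_id")
  if (nrow(m) != nrow(classifications))
    stop("join failure: classified bats missing from the truth table",
         call. = FALSE)
  conf <- table(
    truth = factor(ifelse(m$is_migrant, "migrant", "sedentary"),
                   levels = c("sedentary", "migrant")),
    call = factor(m$combined, levels = c("local", "non-local")))
  sens <- if (sum(conf["migrant", ]) > 0)
    conf["migrant", "non-local"] / sum(conf["migrant", ]) else NA_real_
  spec <- if (sum(conf["sedentary", ]) > 0)
    conf["sedentary", "local"] / sum(conf["sedentary", ]) else NA_real_
  list(confusion = conf, sensitivity = sens, specificity = spec)
}
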