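# Fixture builders shared across test files. All randomness is seeded at the
# call site so each test controls its own reproducibility.

# A minimal 1-cell-resolution grid object with hand-chosen means/variances:
# lat rows south->north, lon columns west->east.
manual_grid <- function(mean_mat, var_mat = NULL, bbox = NULL, res = 1) {
  n_lat <- nrow(mean_mat); n_lon <- ncol(mean_mat)
  if (is.null(bbox)) bbox <- c(0, 40, n_lon * res, 40 + n_lat * res)
  if (is.null(var_mat)) var_mat <- matrix(1, n_lat, n_lon)
  structure(list(
    bbox = bbox, resolution_deg = res,
    lon = bbox[1] + (seq_len(n_lon) - 0.5) * res,
    lat = bbox[2] + (seq_len(n_lat) - 0.5) * res,
    mean = mean_mat, var = var_mat,
    model_params = list()), class = "isoscape_grid")
}

# Long-format bat rows for one bat.
bat_rows <- function(bat_id, fur = NA, wing = NA, site_id = "S1",
                     lon = 0.5, lat = 40.5, season = "autumn",
                     sex = "female") {
  rows <- list()
  if (!is.na(fur))
    rows$fur <- data.frame(bat_id = bat_id, site_id = site_id, lon = lon,
                           lat = lat, season = season, sex = sex,
                           tissue = "fur", d2h = fur)
  if (!is.na(wing))
    rows$wing <- data.frame(bat_id = bat_id, site_id = site_id, lon = lon,
                            lat = lat, season = season, sex = sex,
                            tissue = "wing", d2h = wing)
  do.call(rbind, unname(rows))
}

# Station summaries drawn from a known spatial model: linear-in-lat trend
# plus exponential-covariance field plus nugget noise.
gen_stations <- function(n, seed, base = 38, lat_gradient = -2,
                         elevation_gradient = -0.015, partial_sill = 16,
                         range_km = 300, nugget = 4,
                         bbox = c(-12, 34, 30, 48)) {
  set.seed(seed)
  st <- data.frame(
    station_id = sprintf("ST%03d", seq_len(n)),
    lon = runif(n, bbox[1], bbox[3]),
    lat = runif(n, bbox[2], bbox[4]),
    elevation = pmin(rexp(n, 1 / 300), 2500))
  g <- if (partial_sill > 0) {
    D <- isoassign:::gc_distm_km(cbind(st$lon, st$lat))
    S <- partial_sill * exp(-D / range_km)
    diag(S) <- diag(S) + 1e-8
    drop(t(chol(S)) %*% rnorm(n))
  } else 0
  st$mean_d2h <- base + lat_gradient * st$lat +
    elevation_gradient * st$elevation + g + rnorm(n, 0, sqrt(nugget))
  st
}

# Per-bat synthetic table for the mixed-model simulations: two tissue rows
# per bat, random site and individual intercepts, optional fixed effects.
gen_lmm_table <- function(seed, n_bats = 200, n_sites = 10,
                          tissue_offset = 0, season_offset = 2,
                          sex_offset = 0, site_sd = 3, bat_sd = 3,
                          resid_sd = 3) {
  set.seed(seed)
  site <- sprintf("S%02d", sample.int(n_sites, n_bats, replace = TRUE))
  site_eff <- setNames(rnorm(n_sites, 0, site_sd),
                       sprintf("S%02d", seq_len(n_sites)))
  bat_eff <- rnorm(n_bats, 0, bat_sd)
  season <- sample(c("spring", "autumn"), n_bats, replace = TRUE)
  sex <- sample(c("male", "female"), n_bats, replace = TRUE)
  base <- -30 + site_eff[site] + bat_eff +
    ifelse(season == "spring", season_offset, 0) +
    ifelse(sex == "female", sex_offset, 0)
  data.frame(
    bat_id = rep(sprintf("B%04d", seq_len(n_bats)), 2),
    site_id = rep(site, 2), season = rep(season, 2), sex = rep(sex, 2),
    tissue = rep(c("fur", "wing"), each = n_bats),
    d2h = c(base + rnorm(n_bats, 0, resid_sd),
            base + tissue_offset + rnorm(n_bats, 0, resid_sd)),
    stringsAsFactors = FALSE)
}

# One-row-per-bat table for the fur-wing difference model.
gen_delta_table <- function(seed, n_bats = 150, n_sites = 10,
                            season_offset = 0, sex_offset = 0,
                            site_sd = 1, resid_sd = 2) {
  set.seed(seed)
  site <- sprintf("S%02d", sample.int(n_sites, n_bats, replace = TRUE))
  site_eff <- setNames(rnorm(n_sites, 0, site_sd),
                       sprintf("S%02d", seq_len(n_sites)))
  season <- sample(c("spring", "autumn"), n_bats, replace = TRUE)
  sex <- sample(c("male", "female"), n_bats, replace = TRUE)
  data.frame(
    bat_id = sprintf("B%04d", seq_len(n_bats)),
    site_id = site, season = season, sex = sex,
    delta_d2h = 5 + site_eff[site] +
      ifelse(season == "spring", season_offset, 0) +
      ifelse(sex == "female", sex_offset, 0) +
      rnorm(n_bats, 0, resid_sd),
    stringsAsFactors = FALSE)
}

# Full pipeline on a synthetic world: returns calls, classifications and the
# world itself.
run_world <- function(cfg, threshold = 1.65, alpha = 0.05,
                      analytical_sd = 1.65, res = 0.5) {
  w <- make_world(cfg)
  ss <- summarize_stations(w$stations, years = cfg$years,
                           months = cfg$months)
  iso <- fit_isoscape(ss)
  grid <- predict_isoscape(iso, cfg$bbox, res)
  cal <- select_calibrators(w$bats, threshold = threshold)
  tfs <- list(fur = fit_transfer(cal, "fur", grid),
              wing = fit_transfer(cal, "wing", grid))
  calls <- locality_calls(w$bats, tfs, grid,
                          analytical_sd = analytical_sd, alpha = alpha)
  list(world = w, iso = iso, grid = grid, calibrators = cal, tfs = tfs,
       calls = calls, classifications = combine_tissues(calls))
}
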