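#' Validate pipeline input tables
#'
#' Schema and range checks on the three input tables before a pipeline run:
#' missing columns, out-of-range coordinates or months, unknown enumerated
#' values, duplicate (bat_id, tissue) rows. Findings are returned as a
#' report; [run_pipeline()] refuses to start on any error-level finding.
#'
#' @param bats,stations,runs optional data.frames (or CSV paths) in the
#'   long bats, GNIP-like station and raw-run schemas.
#' @return data.frame with columns \code{table}, \code{level}
#'   (\code{"error"}/\code{"warning"}) and \code{message}; zero rows when
#'   everything checks out. Attribute \code{ok} is \code{TRUE} when no
#'   error-level finding exists.
#' @export
validate_inputs <- function(bats = NULL, stations = NULL, runs = NULL) {
  findings <- list()
  add <- function(tab, level, msg)
    findings[[length(findings) + 1]] <<- data.frame(
      table = tab, level = level, message = msg, stringsAsFactors = FALSE)
  load_tab <- function(x, tab) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        add(tab, "error", paste("file not found:", x))
        return(NULL)
      }
      x <- read.csv(x, stringsAsFactors = FALSE)
    }
    x
  }
  check_coords <- function(df, tab) {
    if (all(c("lon", "lat") %in% names(df))) {
      if (any(df$lon < -180 | df$lon > 180, na.rm = TRUE))
        add(tab, "error", "longitude outside [-180, 180]")
      if (any(df$lat < -90 | df$lat > 90, na.rm = TRUE))
        add(tab, "error", "latitude outside [-90, 90]")
    }
  }

  bats <- load_tab(bats, "bats")
  if (!is.null(bats)) {
    need <- c("bat_id", "site_id", "lon", "lat", "season", "sex", "tissue",
              "d2h")
    miss <- setdiff(need, names(bats))
    if (length(miss))
      add("bats", "error",
          paste("missing columns:", paste(miss, collapse = ", ")))
    else {
      check_coords(bats, "bats")
      bad <- setdiff(unique(bats$tissue), c("fur", "wing"))
      if (length(bad))
        add("bats", "error",
            paste("unknown tissue:", paste(bad, collapse = ", ")))
      dup <- duplicated(bats[, c("bat_id", "tissue")])
      if (any(dup))
        add("bats", "error",
            paste("duplicate (bat_id, tissue) rows:",
                  paste(unique(bats$bat_id[dup]), collapse = ", ")))
      if (any(!is.finite(parse_permil(bats$d2h))))
        add("bats", "error", "non-finite d2h values")
      bad_season <- setdiff(unique(bats$season), c("spring", "autumn"))
      if (length(bad_season))
        add("bats", "warning",
            paste("unexpected season:", paste(bad_season, collapse = ", ")))
    }
  }

  stations <- load_tab(stations, "stations")
  if (!is.null(stations)) {
    need <- c("station_id", "lon", "lat", "elevation", "year", "month",
              "d2h")
    miss <- setdiff(need, names(stations))
    if (length(miss))
      add("stations", "error",
          paste("missing columns:", paste(miss, collapse = ", ")))
    else {
      check_coords(stations, "stations")
      if (any(stations$month < 1 | stations$month > 12))
        add("stations", "error", "month outside 1..12")
      if ("precip_mm" %in% names(stations) &&
          any(stations$precip_mm < 0, na.rm = TRUE))
        add("stations", "error", "negative precipitation amounts")
    }
  }

  runs <- load_tab(runs, "runs")
  if (!is.null(runs)) {
    need <- c("run_id", "sample_id", "role", "raw_d2h")
    miss <- setdiff(need, names(runs))
    if (length(miss))
      add("runs", "error",
          paste("missing columns:", paste(miss, collapse = ", ")))
    else {
      bad <- setdiff(unique(runs$role), c("sample", "reference", "qc"))
      if (length(bad))
        add("runs", "error",
            paste("unknown role:", paste(bad, collapse = ", ")))
    }
  }

  report <- if (length(findings)) do.call(rbind, findings)
  else data.frame(table = character(), level = character(),
                  message = character(), stringsAsFactors = FALSE)
  attr(report, "ok") <- !any(report$level == "error")
  report
}

#' Run the full assignment pipeline
#'
#' Sequences the pipeline end to end: station aggregation, isoscape fit and
#' grid prediction, calibrator selection, transfer-function fits, per-sample
#' locality calls, per-bat classification, site-season summaries, tissue
#' agreement and the two mixed-model analyses. All outputs are written as
#' plain CSV/JSON under \code{out_dir} together with a manifest recording
#' inputs, parameters and every file written.
#'
#' @param bats long-format bat table (or CSV path).
#' @param stations monthly station table (or CSV path).
#' @param out_dir output directory (created if needed); \code{NULL} skips
#'   writing.
#' @param years,months station filter passed to [summarize_stations()].
#' @param bbox,resolution_deg assignment grid geometry; bbox defaults to the
#'   station bounding box padded by one cell.
#' @param threshold calibrator-selection threshold (per-mil), default 1.65.
#' @param alpha assignment significance level, default 0.05.
#' @param analytical_sd analytical SD (per-mil), default 1.65.
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return (invisibly) a list with all stage results: \code{station_summary},
#'   \code{isoscape}, \code{grid}, \code{calibrators}, \code{transfer},
#'   \code{calls}, \code{classifications}, \code{site_summary},
#'   \code{agreement}, \code{lmm}, \code{manifest}.
#' @export
run_pipeline <- function(bats, stations, out_dir = NULL,
                         years = c(2005, 2017), months = 6:8,
                         bbox = NULL, resolution_deg = 0.5,
                         threshold = 1.65, alpha = 0.05,
                         analytical_sd = 1.65, seed = 1) {
  if (is.character(bats)) bats <- read.csv(bats, stringsAsFactors = FALSE)
  if (is.character(stations))
    stations <- read.csv(stations, stringsAsFactors = FALSE)
  report <- validate_inputs(bats = bats, stations = stations)
  if (!attr(report, "ok")) {
    print(report)
    stop("input validation failed; pipeline not started", call. = FALSE)
  }

  station_summary <- summarize_stations(stations, years = years,
                                        months = months)
  iso <- fit_isoscape(station_summary)
  if (is.null(bbox)) {
    r <- resolution_deg
    bbox <- c(floor(min(c(stations$lon, bats$lon)) / r) * r,
              floor(min(c(stations$lat, bats$lat)) / r) * r,
              ceiling(max(c(stations$lon, bats$lon)) / r) * r + r,
              ceiling(max(c(stations$lat, bats$lat)) / r) * r + r)
  }
  grid <- predict_isoscape(iso, bbox, resolution_deg)

  calibrators <- select_calibrators(bats, threshold = threshold)
  transfer <- list(fur = fit_transfer(calibrators, "fur", grid),
                   wing = fit_transfer(calibrators, "wing", grid))
  calls <- locality_calls(bats, transfer, grid,
                          analytical_sd = analytical_sd, alpha = alpha)
  classifications <- combine_tissues(calls)
  site_summary <- summarize_sites(classifications)
  agreement <- tissue_agreement(classifications)

  dd <- delta_diff(bats)
  first <- bats[!duplicated(bats$bat_id),
                c("bat_id", "site_id", "season", "sex")]
  diff_table <- merge(dd, first, by = "bat_id", sort = FALSE)
  lmm <- list(
    tissue = lmm_lrt(bats, "tissue"),
    season = lmm_lrt(bats, "season"),
    sex = if (length(unique(bats$sex)) > 1) lmm_lrt(bats, "sex") else NULL,
    delta_season = delta_lmm_lrt(diff_table, "season"),
    delta_sex = if (length(unique(diff_table$sex)) > 1)
      delta_lmm_lrt(diff_table, "sex") else NULL
  )
  lmm <- lmm[!vapply(lmm, is.null, logical(1))]
  lmm_table <- data.frame(
    term = names(lmm),
    chisq = vapply(lmm, `[[`, numeric(1), "chisq"),
    df = vapply(lmm, `[[`, numeric(1), "df"),
    p = vapply(lmm, `[[`, numeric(1), "p"),
    row.names = NULL, stringsAsFactors = FALSE)

  manifest <- list(
    parameters = list(years = years, months = months, bbox = bbox,
                      resolution_deg = resolution_deg,
                      threshold = threshold, alpha = alpha,
                      analytical_sd = analytical_sd, seed = seed),
    n_stations = nrow(station_summary),
    n_bats = length(unique(bats$bat_id)),
    n_calibrators = length(unique(calibrators$bat_id)),
    isoscape = grid$model_params,
    outputs = character()
  )

  out <- list(station_summary = station_summary, isoscape = iso,
              grid = grid, calibrators = calibrators, transfer = transfer,
              calls = calls, classifications = classifications,
              site_summary = site_summary, agreement = agreement,
              lmm = lmm, lmm_table = lmm_table, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      path <- file.path(out_dir, name)
      write.csv(df, path, row.names = FALSE)
      manifest$outputs <<- c(manifest$outputs, name)
    }
    wr(as.data.frame(grid), "isoscape.csv")
    wr(calls, "calls.csv")
    wr(classifications, "classifications.csv")
    wr(site_summary, "site_summary.csv")
    wr(lmm_table, "lmm.csv")
    tf_json <- lapply(transfer, function(tf)
      tf[c("tissue", "slope", "intercept", "resid_var", "n_calibrators",
           "df")])
    jsonlite::write_json(tf_json, file.path(out_dir, "transfer.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$outputs <- c(manifest$outputs, "transfer.json", "manifest.json")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest
  }
  invisible(out)
}
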