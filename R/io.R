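# Readers and writers for AmeriFlux-style half-hourly delimited text, LAI
# daily averaging, and the end-to-end pipeline driver.

#' Read an AmeriFlux-style half-hourly table
#'
#' Parses a comma-delimited half-hourly file with \code{TIMESTAMP_START} /
#' \code{TIMESTAMP_END} columns in \code{YYYYMMDDHHMM} (local standard
#' time), converts the \code{-9999} sentinel to NA, optionally renames
#' columns through a user map, and checks timestamp monotonicity.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping file column
#'   names to canonical names (\code{c(file_name = "CANONICAL")}).
#' @param required columns that must be present after mapping.
#' @return data.frame with a POSIXct \code{timestamp} column (end of
#'   interval) plus the data columns.
#' @export
read_halfhourly <- function(path, column_map = NULL,
                            required = c("TA", "RH", "PA", "WS", "USTAR")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- column_map[names(df)[hit]]
  }
  if (!all(c("TIMESTAMP_START", "TIMESTAMP_END") %in% names(df)))
    stop("TIMESTAMP_START / TIMESTAMP_END columns are required")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing mandatory columns: ",
                         paste(miss, collapse = ", "))
  ts <- as.POSIXct(as.character(df$TIMESTAMP_END), format = "%Y%m%d%H%M",
                   tz = "UTC")
  if (any(is.na(ts))) stop("unparseable TIMESTAMP_END values")
  if (any(diff(as.numeric(ts)) <= 0)) stop("timestamps are not increasing")
  for (col in setdiff(names(df), c("TIMESTAMP_START", "TIMESTAMP_END"))) {
    if (is.numeric(df[[col]])) df[[col]][df[[col]] == -9999] <- NA_real_
  }
  df$timestamp <- ts
  df
}

#' Write a half-hourly table in AmeriFlux-style delimited text
#'
#' Writes \code{TIMESTAMP_START} / \code{TIMESTAMP_END} as
#' \code{YYYYMMDDHHMM} and NA as \code{-9999}.
#'
#' @param df data.frame with a POSIXct \code{timestamp} column (end of
#'   interval).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_halfhourly <- function(df, path) {
  out <- df
  ts <- out$timestamp
  out$timestamp <- NULL
  out <- cbind(
    TIMESTAMP_START = format(ts - 1800, "%Y%m%d%H%M", tz = "UTC"),
    TIMESTAMP_END = format(ts, "%Y%m%d%H%M", tz = "UTC"),
    out)
  num <- vapply(out, is.numeric, logical(1))
  for (col in names(out)[num]) out[[col]][is.na(out[[col]])] <- -9999
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Daily leaf area index from repeated samples
#'
#' Averages the per-location LAI samples taken on one day after removing
#' outliers beyond 1.5 interquartile ranges from the median (median-centered
#' Tukey fences, which stay meaningful for the typical three samples per
#' day).
#'
#' @param samples numeric LAI samples, m2 m-2 (>= 1 value).
#' @return the daily site LAI.
#' @export
#' @examples
#' daily_lai(c(4.0, 4.2, 9.9))  # outlier dropped -> 4.1
daily_lai <- function(samples) {
  samples <- samples[!is.na(samples)]
  if (!length(samples)) stop("need at least one LAI sample")
  if (length(samples) == 1) return(samples)
  med <- stats::median(samples)
  iqr <- stats::IQR(samples)
  keep <- abs(samples - med) <= 1.5 * iqr
  mean(samples[keep])
}

#' Pipeline configuration
#'
#' Collects the knobs of an end-to-end run. Unknown keys are rejected.
#'
#' @param days length of the simulated season.
#' @param seed RNG seed for the synthetic world.
#' @param params a [truth_params()] object (its seed is overridden by
#'   \code{seed} when given).
#' @param site a [site_meta()] object.
#' @param rain_window_h,rh_max,sza_max conductance filter settings.
#' @param window_days Medlyn window width (days).
#' @param min_obs minimum observations per Medlyn fit.
#' @param run_grid whether to run the 15-filter sensitivity grid.
#' @param medlyn_sqrt_vpd use the square-root VPD Medlyn variant.
#' @param dt_weight time-weighted exposure accumulation.
#' @param start_date first simulated day.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(days = 62, seed = 1L, params = NULL, site = NULL,
                       rain_window_h = 36, rh_max = 80, sza_max = 85,
                       window_days = 10, min_obs = 20L, run_grid = FALSE,
                       medlyn_sqrt_vpd = FALSE, dt_weight = FALSE,
                       start_date = "2023-07-01") {
  if (is.null(params)) params <- truth_params(seed = seed)
  else params$seed <- as.integer(seed)
  if (is.null(site)) site <- site_meta()
  structure(list(days = days, seed = as.integer(seed), params = params,
                 site = site, rain_window_h = rain_window_h,
                 rh_max = rh_max, sza_max = sza_max,
                 window_days = window_days, min_obs = min_obs,
                 run_grid = run_grid, medlyn_sqrt_vpd = medlyn_sqrt_vpd,
                 dt_weight = dt_weight, start_date = start_date),
            class = "run_config")
}

#' Run the full pipeline on a synthetic or supplied half-hourly table
#'
#' Stages: simulate (when no observations are supplied), friction-velocity
#' threshold detection and nighttime filtering, gap filling of NEE,
#' nighttime partitioning into GPP and Reco, the deposition resistance
#' network, the conductance stage (PM inversion + Medlyn fits), daily dose
#' and exposure metrics, seasonal accumulation, and optionally the
#' 15-filter x 2-mode sensitivity grid.
#'
#' @param config a [run_config()] object.
#' @param obs optional half-hourly observation table (as produced by
#'   [simulate_dataset()] or [read_halfhourly()]); when NULL a synthetic
#'   season is generated from the config.
#' @param out_dir optional directory; when given, stage tables, the daily
#'   metrics, the accumulation summary and the resolved configuration are
#'   written there as delimited text / JSON.
#' @return list with \code{obs}, \code{ustar} (change-point result),
#'   \code{partition}, \code{deposition} (the extended table),
#'   \code{conductance}, \code{fits}, \code{daily}, \code{accumulation},
#'   \code{grid} (or NULL), \code{truth} (when simulated), and
#'   \code{exclusions}.
#' @export
run_pipeline <- function(config = run_config(), obs = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  site <- config$site
  truth <- NULL
  if (is.null(obs)) {
    world <- simulate_dataset(config$days, config$params, site,
                              config$start_date)
    obs <- world$obs
    truth <- world$truth
  }
  sol <- solar_position(obs$timestamp - 900, site$latitude, site$longitude,
                        site$utc_offset)
  night <- sol$elevation <= 0

  # u* threshold from nighttime NEE; filter nighttime low-turbulence records
  ustar_res <- tryCatch(
    ustar_changepoint(obs$FC, obs$USTAR, obs$timestamp),
    error = function(e) list(threshold = NA_real_, by_month = NULL,
                             reliable = FALSE))
  nee <- obs$FC
  if (is.finite(ustar_res$threshold) && ustar_res$reliable) {
    nee[night & obs$USTAR < ustar_res$threshold] <- NA_real_
  }

  vpd <- saturation_vapor_pressure(obs$TA) - vapor_pressure(obs$TA, obs$RH)
  gf <- gapfill_lut(nee, obs$timestamp, obs$SW_IN, obs$TA, vpd)
  part <- partition_nee(gf$filled, obs$TA, obs$timestamp, night)

  tab <- obs
  tab$GPP <- part$data$GPP
  tab$RECO <- part$data$RECO
  tab$NEE <- part$data$NEE
  tab$FILL_FLAG <- gf$flag

  tab <- add_deposition(tab, site)
  cond <- add_conductance(tab, site,
                          rain_window_h = config$rain_window_h,
                          rh_max = config$rh_max, sza_max = config$sza_max,
                          window_days = config$window_days,
                          min_obs = config$min_obs,
                          sqrt_vpd = config$medlyn_sqrt_vpd)
  daily <- daily_dose(cond$data, dt_weight = config$dt_weight)
  acc <- accumulate_metrics(daily)
  grid <- if (isTRUE(config$run_grid)) sensitivity_grid(
    tab, site, window_days = config$window_days,
    min_obs = config$min_obs) else NULL

  res <- list(obs = obs, ustar = ustar_res, partition = part,
              deposition = tab, conductance = cond$data, fits = cond$fits,
              daily = daily, accumulation = acc, grid = grid,
              truth = truth, exclusions = cond$exclusions)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_halfhourly(obs, file.path(out_dir, "halfhourly_obs.csv"))
    if (!is.null(truth))
      write_halfhourly(truth, file.path(out_dir, "truth_sidecar.csv"))
    utils::write.csv(daily, file.path(out_dir, "daily_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(acc, file.path(out_dir, "accumulation.csv"),
                     row.names = FALSE)
    utils::write.csv(cond$fits, file.path(out_dir, "medlyn_fits.csv"),
                     row.names = FALSE)
    if (!is.null(grid))
      utils::write.csv(grid$cells, file.path(out_dir, "sensitivity_grid.csv"),
                       row.names = FALSE)
    cfg <- config
    cfg$params <- unclass(cfg$params)
    cfg$site <- unclass(cfg$site)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
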