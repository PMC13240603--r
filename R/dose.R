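# Flux-based phytotoxic ozone dose (POD6) and concentration-based exposure
# indices (AOT40, W126), diurnal centroids, seasonal accumulation with
# intersection-day accounting, and the filter sensitivity grid.

#' Stomatal ozone flux from the conductance ratio
#'
#' \code{Flux_stom = (Gs_O3 / Gc_O3) Vd [O3]}; the total flux is
#' \code{Vd [O3]} and the stomatal fraction equals the conductance ratio.
#' Ratios outside the closed interval [0, 1] are excluded (NA with reason).
#'
#' @param ratio stomatal-to-bulk ozone conductance ratio.
#' @param vd deposition velocity, m s-1.
#' @param conc ozone molar density, nmol m-3.
#' @return data.frame with \code{flux_stom}, \code{flux_total}
#'   (nmol m-2 s-1), \code{frac}, and logical \code{excluded}.
#' @export
#' @examples
#' stomatal_o3_flux(0.5, 0.006, 1634.9)
stomatal_o3_flux <- function(ratio, vd, conc) {
  bad <- is.na(ratio) | ratio < 0 | ratio > 1 | is.na(vd) | is.na(conc) |
    conc <= 0
  total <- vd * conc
  stom <- ifelse(bad, NA_real_, ratio * total)
  data.frame(flux_stom = stom,
             flux_total = ifelse(is.na(vd) | is.na(conc), NA_real_, total),
             frac = ifelse(bad, NA_real_, ratio),
             excluded = bad)
}

#' Diurnal centroid of a variable
#'
#' The value-weighted mean decimal hour over a daylight window:
#' \code{sum(v_t t) / sum(v_t)}. Requires at least \code{min_points} valid
#' samples inside the window and a positive weight sum; otherwise NA.
#'
#' @param values half-hourly values for one day (non-negative weights).
#' @param hours decimal hour of each sample.
#' @param window daylight window, default \code{c(7, 17)}.
#' @param min_points minimum valid samples in the window.
#' @return decimal hour, or NA.
#' @export
#' @examples
#' h <- seq(7, 17, by = 0.5)
#' diurnal_centroid(rep(1, length(h)), h)  # 12
diurnal_centroid <- function(values, hours, window = c(7, 17),
                             min_points = 9L) {
  inw <- hours >= window[1] & hours <= window[2] & !is.na(values)
  if (sum(inw) < min_points) return(NA_real_)
  v <- values[inw]
  if (any(v < 0)) {
    inw[inw][values[inw] < 0] <- FALSE
    v <- values[inw]
    if (sum(inw) < min_points) return(NA_real_)
  }
  s <- sum(v)
  if (s <= 0) return(NA_real_)
  sum(v * hours[inw]) / s
}

#' Daily phytotoxic ozone dose above 6 nmol m-2 s-1
#'
#' \code{POD6 = sum(max(0, flux - 6) * 1800)} over daytime half hours,
#' converted from nmol to micromol m-2.
#'
#' @param flux_stom stomatal ozone flux, nmol m-2 s-1 (daytime half hours;
#'   NAs are skipped).
#' @param threshold detoxification threshold, nmol m-2 s-1.
#' @return micromol m-2.
#' @export
#' @examples
#' pod6_daily(c(8, 5, 10))  # 10.8
pod6_daily <- function(flux_stom, threshold = 6) {
  sum(pmax(0, flux_stom - threshold) * 1800, na.rm = TRUE) / 1000
}

#' Daily AOT40
#'
#' Accumulated ozone exceedance over 40 ppb across daytime samples. The
#' half-hourly dialect sums per-sample exceedances with no half-hour weight
#' (the units follow the convention of reporting the sum in ppb h); the
#' hourly-mean dialect first averages the half hours of each clock hour.
#'
#' @param conc_ppb ozone mixing ratios, ppb (daytime half hours).
#' @param hour integer clock hour per sample (needed for the hourly dialect).
#' @param dialect \code{"halfhourly"} or \code{"hourly_mean"}.
#' @param dt_weight if TRUE multiply each half-hourly exceedance by 0.5 h
#'   (standards-compliant time weighting; default off, matching the
#'   per-sample accumulation).
#' @param threshold ppb.
#' @return ppb h.
#' @export
#' @examples
#' aot40_daily(c(50, 30, 45))  # 15
aot40_daily <- function(conc_ppb, hour = NULL,
                        dialect = c("halfhourly", "hourly_mean"),
                        dt_weight = FALSE, threshold = 40) {
  dialect <- match.arg(dialect)
  if (dialect == "hourly_mean") {
    if (is.null(hour)) stop("hourly_mean dialect needs clock hours")
    conc_ppb <- tapply(conc_ppb, hour, mean, na.rm = TRUE)
  }
  w <- if (dt_weight) (if (dialect == "halfhourly") 0.5 else 1) else 1
  sum(pmax(0, conc_ppb - threshold) * w, na.rm = TRUE)
}

#' W126 sigmoidal weight
#'
#' \code{W = 1 / (1 + M exp(-A [O3]/1000))} with M = 4403, A = 126.
#'
#' @param conc_ppb ozone mixing ratio, ppb.
#' @param m,a weighting constants.
#' @return weight in (0, 1).
#' @export
#' @examples
#' w126_weight(100)  # about 0.9854
#' w126_weight(0)    # about 2.27e-4
w126_weight <- function(conc_ppb, m = 4403, a = 126) {
  1 / (1 + m * exp(-a * conc_ppb / 1000))
}

#' Daily W126
#'
#' Sigmoid-weighted ozone sum \code{sum(W_i [O3]_i)} over daytime samples,
#' with the same dialect options as [aot40_daily()]. Reported in ppb h by
#' the per-sample convention.
#'
#' @inheritParams aot40_daily
#' @return ppb h.
#' @export
w126_daily <- function(conc_ppb, hour = NULL,
                       dialect = c("halfhourly", "hourly_mean"),
                       dt_weight = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "hourly_mean") {
    if (is.null(hour)) stop("hourly_mean dialect needs clock hours")
    conc_ppb <- tapply(conc_ppb, hour, mean, na.rm = TRUE)
  }
  w <- if (dt_weight) (if (dialect == "halfhourly") 0.5 else 1) else 1
  sum(w126_weight(conc_ppb) * conc_ppb * w, na.rm = TRUE)
}

#' Daily dose and exposure table
#'
#' Computes, for each calendar day: POD6 from both stomatal flux estimates,
#' AOT40 and W126 from concentrations, diurnal centroids of ozone, both
#' stomatal conductances, the total ozone flux and both stomatal fluxes,
#' and valid-sample counts. Daytime is solar zenith angle < 90 degrees
#' (configurable); centroids use the daylight window and the minimum-point
#' rule.
#'
#' @param df conductance-stage table with columns \code{timestamp},
#'   \code{O3}, \code{VD_O3}, \code{O3_DENS}, \code{RATIO_MED},
#'   \code{RATIO_PM}, \code{GS_O3_MED}, \code{GS_O3_PM}, \code{SZA}.
#' @param daylight_sza zenith angle below which a half hour counts as
#'   daytime for the accumulation metrics.
#' @param centroid_window daylight window for centroids, decimal hours.
#' @param min_points_centroid minimum samples per day for a centroid.
#' @param dialect,dt_weight accumulation dialect, see [aot40_daily()].
#' @return data.frame with one row per day.
#' @export
daily_dose <- function(df, daylight_sza = 90, centroid_window = c(7, 17),
                       min_points_centroid = 9L,
                       dialect = "halfhourly", dt_weight = FALSE) {
  stopifnot(all(c("timestamp", "O3", "VD_O3", "O3_DENS", "RATIO_MED",
                  "RATIO_PM", "SZA") %in% names(df)))
  mid <- df$timestamp - 900
  date <- as.Date(mid, tz = "UTC")
  hour <- as.numeric(format(mid, "%H", tz = "UTC")) +
    as.numeric(format(mid, "%M", tz = "UTC")) / 60
  clock_hour <- floor(hour)
  day <- !is.na(df$SZA) & df$SZA < daylight_sza

  med <- stomatal_o3_flux(df$RATIO_MED, df$VD_O3, df$O3_DENS)
  pm <- stomatal_o3_flux(df$RATIO_PM, df$VD_O3, df$O3_DENS)

  rows <- lapply(split(seq_len(nrow(df)), date), function(ii) {
    d <- day[ii]
    conc <- ifelse(d, df$O3[ii], NA_real_)
    fs_med <- ifelse(d, med$flux_stom[ii], NA_real_)
    fs_pm <- ifelse(d, pm$flux_stom[ii], NA_real_)
    ft <- ifelse(d, med$flux_total[ii], NA_real_)
    data.frame(
      date = date[ii][1],
      pod6_med = pod6_daily(fs_med),
      pod6_pm = pod6_daily(fs_pm),
      aot40 = aot40_daily(conc, clock_hour[ii], dialect, dt_weight),
      w126 = w126_daily(conc, clock_hour[ii], dialect, dt_weight),
      n_conc = sum(!is.na(conc)),
      n_stom_med = sum(!is.na(fs_med)),
      n_stom_pm = sum(!is.na(fs_pm)),
      centroid_o3 = diurnal_centroid(conc, hour[ii], centroid_window,
                                     min_points_centroid),
      centroid_gs_med = diurnal_centroid(df$GS_O3_MED[ii], hour[ii],
                                         centroid_window,
                                         min_points_centroid),
      centroid_gs_pm = diurnal_centroid(df$GS_O3_PM[ii], hour[ii],
                                        centroid_window,
                                        min_points_centroid),
      centroid_fo3 = diurnal_centroid(ft, hour[ii], centroid_window,
                                      min_points_centroid),
      centroid_fstom_med = diurnal_centroid(fs_med, hour[ii],
                                            centroid_window,
                                            min_points_centroid),
      centroid_fstom_pm = diurnal_centroid(fs_pm, hour[ii],
                                           centroid_window,
                                           min_points_centroid)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Seasonal accumulation with intersection-day accounting
#'
#' Sums the daily metrics over the study window in three day-set variants:
#' all days with valid concentration data, the days on which the
#' Medlyn-based POD6 could be computed, and the days on which the PM-based
#' POD6 could be computed. POD6 sums are reported in mmol m-2 and AOT40 /
#' W126 in ppm h (matching the scale the seasonal totals are conventionally
#' reported in).
#'
#' @param daily output of [daily_dose()].
#' @param min_samples_day minimum valid half hours for a day to count
#'   toward a metric.
#' @return data.frame with one row per variant (\code{all},
#'   \code{intersect_med}, \code{intersect_pm}): day counts and sums.
#' @export
accumulate_metrics <- function(daily, min_samples_day = 5L) {
  if (nrow(daily) == 0) {
    return(data.frame(variant = c("all", "intersect_med", "intersect_pm"),
                      n_days = 0L, pod6_med = 0, pod6_pm = 0,
                      aot40 = 0, w126 = 0))
  }
  conc_ok <- daily$n_conc >= min_samples_day
  med_ok <- conc_ok & daily$n_stom_med >= min_samples_day
  pm_ok <- conc_ok & daily$n_stom_pm >= min_samples_day
  sum_over <- function(sel) {
    data.frame(n_days = sum(sel),
               pod6_med = sum(daily$pod6_med[sel & med_ok]) / 1000,
               pod6_pm = sum(daily$pod6_pm[sel & pm_ok]) / 1000,
               aot40 = sum(daily$aot40[sel]) / 1000,
               w126 = sum(daily$w126[sel]) / 1000)
  }
  out <- rbind(cbind(variant = "all", sum_over(conc_ok)),
               cbind(variant = "intersect_med", sum_over(med_ok)),
               cbind(variant = "intersect_pm", sum_over(pm_ok)))
  rownames(out) <- NULL
  out
}

#' The 15-member filter grid
#'
#' Enumerates the post-precipitation exclusion windows (24, 36, 48, 60,
#' 72 h) crossed with the relative humidity thresholds (70, 80, 90 percent).
#'
#' @return data.frame with columns \code{filter_id}, \code{rain_window_h},
#'   \code{rh_max} (15 rows).
#' @export
filter_grid <- function() {
  g <- expand.grid(rain_window_h = c(24, 36, 48, 60, 72),
                   rh_max = c(70, 80, 90))
  g$filter_id <- seq_len(nrow(g))
  g[, c("filter_id", "rain_window_h", "rh_max")]
}

#' Filter and parameter-mode sensitivity grid
#'
#' Re-runs the conductance and dose stages for each of the 15 data filters
#' and for both Medlyn parameter modes (10-day moving fits and a season-wide
#' fixed fit), accumulating POD6, AOT40 and W126 on the intersection day
#' sets for each cell. Returns 30 rows plus min/max bounds per metric.
#'
#' @param df half-hourly table with deposition columns and GPP (the input
#'   normally given to [add_conductance()]).
#' @param site a [site_meta()] object.
#' @param window_days Medlyn window for the moving mode.
#' @param min_obs minimum observations per Medlyn window.
#' @param min_samples_day day-validity rule for accumulation.
#' @param constants list from [flux_constants()].
#' @return list with \code{cells} (30-row data.frame) and \code{bounds}
#'   (min/max of each accumulated metric across cells).
#' @export
sensitivity_grid <- function(df, site = site_meta(), window_days = 10,
                             min_obs = 20L, min_samples_day = 5L,
                             constants = flux_constants()) {
  grid <- filter_grid()
  modes <- c("moving", "fixed")
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    for (mode in modes) {
      wd <- if (mode == "moving") window_days else Inf
      cond <- add_conductance(df, site,
                              rain_window_h = grid$rain_window_h[i],
                              rh_max = grid$rh_max[i],
                              window_days = wd, min_obs = min_obs,
                              constants = constants)
      if (nrow(cond$fits) == 0 || !any(cond$fits$converged)) {
        rows[[length(rows) + 1]] <- data.frame(
          filter_id = grid$filter_id[i],
          rain_window_h = grid$rain_window_h[i], rh_max = grid$rh_max[i],
          mode = mode, available = FALSE,
          n_days_med = NA_integer_, n_days_pm = NA_integer_,
          pod6_med = NA_real_, pod6_pm = NA_real_,
          aot40_med = NA_real_, w126_med = NA_real_,
          aot40_pm = NA_real_, w126_pm = NA_real_)
        next
      }
      daily <- daily_dose(cond$data)
      acc <- accumulate_metrics(daily, min_samples_day)
      amed <- acc[acc$variant == "intersect_med", ]
      apm <- acc[acc$variant == "intersect_pm", ]
      rows[[length(rows) + 1]] <- data.frame(
        filter_id = grid$filter_id[i],
        rain_window_h = grid$rain_window_h[i], rh_max = grid$rh_max[i],
        mode = mode, available = TRUE,
        n_days_med = amed$n_days, n_days_pm = apm$n_days,
        pod6_med = amed$pod6_med, pod6_pm = apm$pod6_pm,
        aot40_med = amed$aot40, w126_med = amed$w126,
        aot40_pm = apm$aot40, w126_pm = apm$w126)
    }
  }
  cells <- do.call(rbind, rows)
  metric_cols <- c("pod6_med", "pod6_pm", "aot40_med", "w126_med",
                   "aot40_pm", "w126_pm")
  bounds <- data.frame(
    metric = metric_cols,
    min = vapply(metric_cols, function(m) min(cells[[m]], na.rm = TRUE),
                 numeric(1)),
    max = vapply(metric_cols, function(m) max(cells[[m]], na.rm = TRUE),
                 numeric(1)))
  rownames(bounds) <- NULL
  list(cells = cells, bounds = bounds)
}
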