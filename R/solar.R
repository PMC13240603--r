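#' Solar position for half-hourly timestamps
#'
#' NOAA-style solar geometry: fractional-year declination and equation of
#' time, true solar time from longitude and the clock's UTC offset, then the
#' zenith angle from the hour angle. Accuracy is a fraction of a degree,
#' which is ample for daylight masks and a solar zenith angle cutoff.
#'
#' @param time POSIXct timestamps in local standard time (no DST).
#' @param lat latitude, degrees north.
#' @param lon longitude, degrees east (negative west).
#' @param utc_offset hours the local clock is ahead of UTC (negative west).
#' @return data.frame with columns \code{zenith} and \code{elevation}
#'   (degrees) and \code{declination} (degrees).
#' @export
solar_position <- function(time, lat, lon, utc_offset) {
  doy <- as.integer(strftime(time, "%j", tz = attr(time, "tzone") %||% "UTC"))
  hour <- as.numeric(strftime(time, "%H", tz = attr(time, "tzone") %||% "UTC")) +
    as.numeric(strftime(time, "%M", tz = attr(time, "tzone") %||% "UTC")) / 60
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)  # fractional year, rad
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))  # minutes
  # true solar time in minutes
  tst <- hour * 60 + eqtime + 4 * lon - 60 * utc_offset
  ha <- (tst / 4 - 180) * pi / 180  # hour angle, rad
  lat_r <- lat * pi / 180
  cos_zen <- sin(lat_r) * sin(decl) + cos(lat_r) * cos(decl) * cos(ha)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  zen <- acos(cos_zen) * 180 / pi
  data.frame(zenith = zen, elevation = 90 - zen, declination = decl * 180 / pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Site metadata
#'
#' Container for the tower geometry and location needed by the stability and
#' solar calculations. Defaults describe a rainfed maize field in central
#' Illinois with instruments at 3.5 m and a peak canopy height of 2.05 m.
#'
#' @param latitude,longitude decimal degrees (longitude negative west).
#' @param measurement_height instrument height above ground, m.
#' @param canopy_height canopy height, m (must be below measurement height).
#' @param utc_offset local standard time offset from UTC, hours.
#' @param ca ambient CO2 mole fraction, micromol mol-1.
#' @return A list of class \code{site_meta}.
#' @export
#' @examples
#' site_meta()
site_meta <- function(latitude = 40.0062, longitude = -88.2904,
                      measurement_height = 3.5, canopy_height = 2.05,
                      utc_offset = -6, ca = 420) {
  stopifnot(measurement_height > canopy_height, canopy_height > 0, ca > 0)
  structure(list(latitude = latitude, longitude = longitude,
                 measurement_height = measurement_height,
                 canopy_height = canopy_height,
                 utc_offset = utc_offset, ca = ca),
            class = "site_meta")
}
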