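# High-frequency (10 Hz) block processing: despiking, coordinate rotation,
# half-hourly covariance fluxes, and steady-state / integral turbulence
# quality flags.

#' Median/MAD despiking
#'
#' Flags samples deviating from the running (windowed) median by more than
#' \code{k_mad} robust standard deviations, computed in non-overlapping
#' windows (default 5 min at 10 Hz). Flagged samples are set to \code{NA} in
#' the returned copy; the input is not modified.
#'
#' @param x numeric series (may contain NA).
#' @param k_mad spike threshold in MAD units.
#' @param window window length in samples.
#' @return list with \code{values} (series with spikes set NA) and
#'   \code{removed} (count of newly masked samples).
#' @export
despike <- function(x, k_mad = 6, window = 3000L) {
  if (length(x) == 0) stop("empty series")
  if (all(is.na(x))) stop("all-missing series")
  out <- x
  idx <- split(seq_along(x), ceiling(seq_along(x) / window))
  removed <- 0L
  for (ii in idx) {
    xi <- x[ii]
    med <- stats::median(xi, na.rm = TRUE)
    madv <- stats::mad(xi, na.rm = TRUE)
    bad <- !is.na(xi) & abs(xi - med) > k_mad * madv
    removed <- removed + sum(bad)
    out[ii][bad] <- NA_real_
  }
  list(values = out, removed = removed)
}

#' Double rotation of the wind vector
#'
#' First rotation (yaw) aligns the mean wind with the streamwise axis so the
#' mean cross-wind component is zero; second rotation (pitch) zeroes the mean
#' vertical velocity. Per-sample vector magnitudes are preserved.
#'
#' @param u,v,w wind components, m s-1 (NAs allowed, propagated).
#' @return list with rotated \code{u}, \code{v}, \code{w} and the rotation
#'   angles \code{yaw} and \code{pitch} in degrees.
#' @export
double_rotation <- function(u, v, w) {
  ok <- !is.na(u) & !is.na(v) & !is.na(w)
  if (sum(ok) < 2) stop("need at least 2 valid wind samples")
  if (all(abs(u[ok]) < 1e-12) && all(abs(v[ok]) < 1e-12))
    stop("degenerate wind: no horizontal flow")
  yaw <- atan2(mean(v[ok]), mean(u[ok]))
  u1 <- u * cos(yaw) + v * sin(yaw)
  v1 <- -u * sin(yaw) + v * cos(yaw)
  pitch <- atan2(mean(w[ok]), mean(u1[ok]))
  u2 <- u1 * cos(pitch) + w * sin(pitch)
  w2 <- -u1 * sin(pitch) + w * cos(pitch)
  list(u = u2, v = v1, w = w2,
       yaw = yaw * 180 / pi, pitch = pitch * 180 / pi)
}

# Eddy-covariance block covariance: mean of products of deviations from the
# block means (population form), over samples where both channels are valid.
block_cov <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  mean((a[ok] - mean(a[ok])) * (b[ok] - mean(b[ok])))
}

#' Half-hourly fluxes from a despiked, rotated block
#'
#' Computes the covariance fluxes \code{Flux_s = mean(w' s')} for the CO2,
#' H2O and O3 channels, sensible heat \code{H = rho cp mean(w' T')}, latent
#' heat from the H2O flux with explicit micromol-to-mol conversion, and the
#' friction velocity \code{ustar = (cov(u,w)^2 + cov(v,w)^2)^(1/4)}.
#'
#' @param block data.frame as from [gen_highfreq_block()] (after despiking
#'   and rotation), columns \code{u,v,w,Ts,c_co2,c_h2o,c_o3}.
#' @param air list with \code{rho} (kg m-3), \code{cp} (J kg-1 K-1) and
#'   \code{lambda_v} (J kg-1); defaults are computed from the block's mean
#'   sonic temperature at standard pressure.
#' @param literal_le if TRUE, apply a 1e-3 factor to the latent heat flux
#'   instead of the unit-consistent 1e-6 micromol-to-mol conversion
#'   (provided only to reproduce a literal published form; default off).
#' @param constants list from [flux_constants()].
#' @return one-row data.frame: \code{FC}, \code{FH2O} (micromol m-2 s-1),
#'   \code{FO3} (nmol m-2 s-1), \code{H}, \code{LE} (W m-2), \code{USTAR},
#'   \code{WS} (m s-1), and per-channel missing fractions \code{MISS_*}.
#'   All fluxes carry the raw covariance (micrometeorological) sign:
#'   deposition of O3 appears as a negative \code{FO3}; the deposition
#'   stage works with the deposition-positive flux \code{-FO3}.
#' @export
block_fluxes <- function(block, air = NULL, literal_le = FALSE,
                         constants = flux_constants()) {
  if (is.null(air)) {
    tmean <- mean(block$Ts, na.rm = TRUE)
    air <- list(rho = air_density(tmean, 50, 101.325, constants),
                cp = specific_heat_air(tmean, 50, 101.325, constants),
                lambda_v = latent_heat_vaporization(tmean))
  }
  cov_uw <- block_cov(block$u, block$w)
  cov_vw <- block_cov(block$v, block$w)
  ustar <- (cov_uw^2 + cov_vw^2)^0.25
  f_co2 <- block_cov(block$w, block$c_co2)
  f_h2o <- block_cov(block$w, block$c_h2o)
  f_o3 <- block_cov(block$w, block$c_o3)
  h <- air$rho * air$cp * block_cov(block$w, block$Ts)
  le <- air$lambda_v * constants$M_h2o * f_h2o *
    (if (literal_le) 1e-3 else 1e-6)
  miss <- vapply(c("u", "v", "w", "Ts", "c_co2", "c_h2o", "c_o3"),
                 function(col) mean(is.na(block[[col]])), numeric(1))
  data.frame(FC = f_co2, FH2O = f_h2o, FO3 = f_o3, H = h, LE = le,
             USTAR = ustar, WS = mean(block$u, na.rm = TRUE),
             MISS_WIND = max(miss[c("u", "v", "w")]),
             MISS_TS = miss[["Ts"]], MISS_CO2 = miss[["c_co2"]],
             MISS_H2O = miss[["c_h2o"]], MISS_O3 = miss[["c_o3"]],
             row.names = NULL)
}

# Map a relative deviation to a quality class: <=30% -> 0, <=100% -> 1, else 2.
deviation_class <- function(dev) {
  ifelse(dev <= 0.30, 0L, ifelse(dev <= 1.00, 1L, 2L))
}

#' Steady-state and integral turbulence characteristics flags
#'
#' Steady-state test: the block is split into six 5-minute sub-intervals and
#' the mean of the sub-interval covariances is compared to the full-block
#' covariance; a relative deviation of at most 30% gives class 0, at most
#' 100% class 1, otherwise class 2. The integral turbulence test compares
#' the measured \code{sigma_w / ustar} to a neutral-limit model value
#' (default 1.3) with the same class bands.
#'
#' @param block data.frame of despiked, rotated high-frequency samples.
#' @param n_sub number of sub-intervals for the steady-state test.
#' @param itc_model neutral-limit value of \code{sigma_w / ustar}.
#' @return list with \code{steady_state} (named integer vector of classes for
#'   Ts, co2, h2o, o3), \code{itc} (integer class), and \code{overall}
#'   (named vector: per-channel max of its steady-state class and the ITC
#'   class).
#' @export
ssitc_flags <- function(block, n_sub = 6L, itc_model = 1.3) {
  n <- nrow(block)
  if (n < 2 * n_sub) stop("too few samples for sub-interval test")
  grp <- ceiling(seq_len(n) / (n / n_sub))
  channels <- c(Ts = "Ts", co2 = "c_co2", h2o = "c_h2o", o3 = "c_o3")
  ss <- vapply(channels, function(col) {
    full <- block_cov(block$w, block[[col]])
    subs <- vapply(split(seq_len(n), grp), function(ii) {
      block_cov(block$w[ii], block[[col]][ii])
    }, numeric(1))
    dev <- abs(mean(subs, na.rm = TRUE) - full) / abs(full)
    deviation_class(dev)
  }, integer(1))
  cov_uw <- block_cov(block$u, block$w)
  cov_vw <- block_cov(block$v, block$w)
  ustar <- (cov_uw^2 + cov_vw^2)^0.25
  sd_w <- stats::sd(block$w, na.rm = TRUE)
  itc <- deviation_class(abs(sd_w / ustar - itc_model) / itc_model)
  list(steady_state = ss, itc = itc,
       overall = pmax(ss, itc))
}

#' Quality screening of half-hourly flux records
#'
#' Removes (sets to NA) each flux for which the corresponding high-frequency
#' channel had more than 10% missing samples or an SSITC class of 2. A half
#' hour with more than 10% missing wind samples loses all fluxes.
#'
#' @param records data.frame of flux records as produced by
#'   [process_highfreq_blocks()], with \code{MISS_*} and \code{SSITC_*}
#'   columns.
#' @param max_missing maximum allowed missing fraction (inclusive bound:
#'   exactly 10% is retained).
#' @return list with \code{records} (screened table) and \code{removed}
#'   (named counts of fluxes removed per reason).
#' @export
qc_screen <- function(records, max_missing = 0.10) {
  fluxes <- list(FC = c("MISS_CO2", "SSITC_CO2"),
                 LE = c("MISS_H2O", "SSITC_H2O"),
                 FO3 = c("MISS_O3", "SSITC_O3"),
                 H = c("MISS_TS", "SSITC_TS"))
  removed <- c(missing = 0L, ssitc = 0L, wind = 0L)
  bad_wind <- !is.na(records$MISS_WIND) & records$MISS_WIND > max_missing
  for (fx in names(fluxes)) {
    if (!fx %in% names(records)) next
    mcol <- fluxes[[fx]][1]; scol <- fluxes[[fx]][2]
    bad_m <- !is.na(records[[mcol]]) & records[[mcol]] > max_missing
    bad_s <- scol %in% names(records) &
      !is.na(records[[scol]]) & records[[scol]] == 2L
    removed["missing"] <- removed["missing"] + sum(bad_m & !bad_wind)
    removed["ssitc"] <- removed["ssitc"] + sum(bad_s & !bad_m & !bad_wind)
    removed["wind"] <- removed["wind"] + sum(bad_wind & !is.na(records[[fx]]))
    records[[fx]][bad_m | bad_s | bad_wind] <- NA_real_
  }
  list(records = records, removed = removed)
}

#' Process a list of high-frequency blocks into a half-hourly flux table
#'
#' For each 30-minute block: despike every channel, double-rotate the wind,
#' compute covariance fluxes and SSITC flags, then screen on missing data
#' and quality classes.
#'
#' @param blocks named list of high-frequency data.frames; names (or the
#'   \code{timestamps} argument) give the half-hour end timestamps.
#' @param timestamps optional POSIXct vector of block end times.
#' @param air optional list(rho, cp, lambda_v) passed to [block_fluxes()].
#' @param k_mad,window despiking parameters, see [despike()].
#' @param screen if TRUE (default) apply [qc_screen()].
#' @return data.frame with one row per block: timestamp, fluxes, ustar,
#'   missing fractions, SSITC classes.
#' @export
process_highfreq_blocks <- function(blocks, timestamps = NULL, air = NULL,
                                    k_mad = 6, window = 3000L,
                                    screen = TRUE) {
  rows <- lapply(blocks, function(b) {
    for (col in c("u", "v", "w", "Ts", "c_co2", "c_h2o", "c_o3"))
      b[[col]] <- despike(b[[col]], k_mad, window)$values
    rot <- double_rotation(b$u, b$v, b$w)
    b$u <- rot$u; b$v <- rot$v; b$w <- rot$w
    fx <- block_fluxes(b, air)
    fl <- ssitc_flags(b)
    fx$SSITC_TS <- fl$overall[["Ts"]]
    fx$SSITC_CO2 <- fl$overall[["co2"]]
    fx$SSITC_H2O <- fl$overall[["h2o"]]
    fx$SSITC_O3 <- fl$overall[["o3"]]
    fx
  })
  out <- do.call(rbind, rows)
  out$timestamp <- if (!is.null(timestamps)) {
    timestamps
  } else {
    parsed <- if (!is.null(names(blocks)))
      tryCatch(as.POSIXct(names(blocks), tz = "UTC"),
               error = function(e) NA) else NA
    if (all(!is.na(parsed))) parsed else
      as.POSIXct("2023-07-01", tz = "UTC") + 1800 * seq_along(blocks)
  }
  if (screen) out <- qc_screen(out)$records
  out
}
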