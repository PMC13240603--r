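# Stomatal conductance two ways: Penman-Monteith inversion of the latent
# heat flux and windowed fits of the Medlyn conductance model driven by GPP,
# both converted to ozone conductances through the diffusivity ratio.

#' Surface (big-leaf) temperature from the sensible heat flux
#'
#' \code{Ts = Tair + H (Ra + Rb_heat) / (rho cp)}.
#'
#' @param tair air temperature, degrees C.
#' @param h sensible heat flux, W m-2.
#' @param rho air density, kg m-3.
#' @param cp specific heat, J kg-1 K-1.
#' @param ra aerodynamic resistance, s m-1.
#' @param rb_heat quasi-laminar resistance to heat, s m-1.
#' @return degrees C.
#' @export
surface_temperature <- function(tair, h, rho, cp, ra, rb_heat) {
  if (any(ra + rb_heat <= 0, na.rm = TRUE)) stop("resistances must be > 0")
  tair + h * (ra + rb_heat) / (rho * cp)
}

#' Canopy-to-air vapor pressure deficit
#'
#' \code{VPDcan = es(Ts) - er}, assuming saturation at the surface.
#' Negative values (vapor pressure above surface saturation, dew-like) are
#' returned as-is; they are flagged and excluded from fits downstream.
#'
#' @param ts surface temperature, degrees C.
#' @param er vapor pressure at measurement height, kPa.
#' @return kPa.
#' @export
canopy_vpd <- function(ts, er) {
  stopifnot(all(er >= 0, na.rm = TRUE))
  saturation_vapor_pressure(ts) - er
}

#' Penman-Monteith inversion for surface conductance
#'
#' Inverts the evaporation-resistance form of the Penman-Monteith equation:
#' \code{Rc = rho cp VPDcan / (gamma lambdaE) - Ra - Rb_h2o}, returning the
#' conductance \code{1/Rc} in m s-1. Records with non-positive latent heat,
#' canopy VPD or derived resistance are returned as NA with a reason code.
#'
#' @param le latent heat flux, W m-2.
#' @param vpdcan canopy-to-air vapor pressure deficit, kPa.
#' @param gamma psychrometric constant, kPa K-1.
#' @param rho air density, kg m-3.
#' @param cp specific heat, J kg-1 K-1.
#' @param ra aerodynamic resistance, s m-1.
#' @param rb_h2o quasi-laminar resistance to water vapor, s m-1.
#' @return data.frame with \code{gs_ms} (m s-1), \code{rc} (s m-1) and
#'   \code{reason} (\code{""} ok, \code{"le"}, \code{"vpdcan"},
#'   \code{"rc_negative"}).
#' @export
pm_inversion <- function(le, vpdcan, gamma, rho, cp, ra, rb_h2o) {
  n <- length(le)
  reason <- character(n)
  reason[is.na(le) | le <= 0] <- "le"
  reason[reason == "" & (is.na(vpdcan) | vpdcan <= 0)] <- "vpdcan"
  rc <- rep(NA_real_, n)
  ok <- reason == ""
  rc[ok] <- rho[ok] * cp[ok] * vpdcan[ok] / (gamma[ok] * le[ok]) -
    ra[ok] - rb_h2o[ok]
  bad_rc <- ok & (is.na(rc) | rc <= 0)
  reason[bad_rc] <- "rc_negative"
  gs <- ifelse(reason == "", 1 / rc, NA_real_)
  rc[reason != ""] <- NA_real_
  data.frame(gs_ms = gs, rc = rc, reason = reason,
             stringsAsFactors = FALSE)
}

#' Validity mask for stomatal conductance estimates
#'
#' A record is valid for conductance work when it is outside every
#' precipitation event and its trailing exclusion window, the solar zenith
#' angle is below \code{sza_max}, and relative humidity is below
#' \code{rh_max} (strict inequalities, so RH exactly at the threshold is
#' excluded).
#'
#' @param timestamp POSIXct timestamps.
#' @param precip precipitation, mm per half hour.
#' @param rh relative humidity, percent.
#' @param sza solar zenith angle, degrees.
#' @param rain_window_h hours excluded after each precipitation event.
#' @param rh_max relative humidity threshold, percent.
#' @param sza_max solar zenith angle threshold, degrees.
#' @return list with \code{valid} (logical), \code{reason} (character:
#'   \code{""}, \code{"rain"}, \code{"sza"}, \code{"rh"}; the first failed
#'   filter in that order), and \code{counts} (exclusions per reason).
#' @export
stomatal_validity_mask <- function(timestamp, precip, rh, sza,
                                   rain_window_h = 36, rh_max = 80,
                                   sza_max = 85) {
  n <- length(timestamp)
  tnum <- as.numeric(timestamp)
  rain_block <- rep(FALSE, n)
  events <- which(!is.na(precip) & precip > 0)
  for (ev in events) {
    rain_block <- rain_block |
      (tnum >= tnum[ev] & tnum <= tnum[ev] + rain_window_h * 3600)
  }
  reason <- character(n)
  reason[rain_block] <- "rain"
  reason[reason == "" & (is.na(sza) | sza >= sza_max)] <- "sza"
  reason[reason == "" & (is.na(rh) | rh >= rh_max)] <- "rh"
  valid <- reason == ""
  list(valid = valid, reason = reason,
       counts = c(rain = sum(reason == "rain"),
                  sza = sum(reason == "sza"),
                  rh = sum(reason == "rh")))
}

#' Fit the Medlyn conductance model in 10-day windows
#'
#' Nonlinear least squares of \code{Gs = G0 + 1.6 (1 + G1/VPDcan) GPP/Ca}
#' (conductance in mol m-2 s-1, Ca converted from micromol mol-1 to a mole
#' fraction by using GPP/Ca directly in mol m-2 s-1) with bounds
#' \code{G0 >= 0}, \code{G1 >= 0}. Windows are consecutive blocks aligned to
#' the first valid observation; blocks with fewer than \code{min_obs} valid
#' records emit no fit. A single season-wide fit is returned when
#' \code{window_days = Inf}.
#'
#' @param gs stomatal conductance to H2O, mol m-2 s-1 (typically the PM
#'   inversion converted to molar units), NA where invalid.
#' @param gpp gross primary productivity, micromol m-2 s-1.
#' @param vpdcan canopy-to-air VPD, kPa.
#' @param timestamp POSIXct timestamps.
#' @param ca ambient CO2, micromol mol-1.
#' @param window_days window width in days (Inf = one season-wide fit).
#' @param min_obs minimum valid observations per window.
#' @param sqrt_vpd if TRUE use the square-root VPD response
#'   \code{1 + G1/sqrt(VPDcan)} instead of the default \code{1 + G1/VPDcan}.
#' @return data.frame of fits: window start/end, \code{g0}, \code{g1},
#'   \code{n_obs}, \code{converged}, \code{resid_sd}.
#' @export
fit_medlyn_windows <- function(gs, gpp, vpdcan, timestamp, ca = 420,
                               window_days = 10, min_obs = 20L,
                               sqrt_vpd = FALSE) {
  ok <- !is.na(gs) & !is.na(gpp) & !is.na(vpdcan) & vpdcan > 0 & gpp >= 0
  if (!any(ok)) return(medlyn_fit_empty())
  tnum <- as.numeric(timestamp)
  t0 <- min(tnum[ok])
  block <- if (is.infinite(window_days)) rep(0L, length(tnum)) else
    as.integer(floor((tnum - t0) / (window_days * 86400)))
  fits <- lapply(split(which(ok), block[ok]), function(ii) {
    if (length(ii) < min_obs) return(NULL)
    d <- data.frame(gs = gs[ii], gpp = gpp[ii], vpd = vpdcan[ii])
    vterm <- if (sqrt_vpd) quote(sqrt(vpd)) else quote(vpd)
    form <- stats::as.formula(
      paste("gs ~ g0 + 1.6 * (1 + g1 /", deparse(vterm), ") * gpp /", ca))
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = d, start = list(g0 = 0.01, g1 = 2),
                        lower = c(0, 0), upper = c(1, 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(start = as.POSIXct(min(tnum[ii]), origin = "1970-01-01",
                                    tz = "UTC"),
                 end = as.POSIXct(max(tnum[ii]), origin = "1970-01-01",
                                  tz = "UTC"),
                 g0 = NA_real_, g1 = NA_real_, n_obs = length(ii),
                 converged = FALSE, resid_sd = NA_real_)
    } else {
      co <- stats::coef(fit)
      data.frame(start = as.POSIXct(min(tnum[ii]), origin = "1970-01-01",
                                    tz = "UTC"),
                 end = as.POSIXct(max(tnum[ii]), origin = "1970-01-01",
                                  tz = "UTC"),
                 g0 = co[["g0"]], g1 = co[["g1"]], n_obs = length(ii),
                 converged = TRUE,
                 resid_sd = stats::sd(stats::residuals(fit)))
    }
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) return(medlyn_fit_empty())
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out
}

medlyn_fit_empty <- function() {
  data.frame(start = as.POSIXct(character(), tz = "UTC"),
             end = as.POSIXct(character(), tz = "UTC"),
             g0 = numeric(), g1 = numeric(), n_obs = integer(),
             converged = logical(), resid_sd = numeric())
}

#' Evaluate the Medlyn model
#'
#' \code{Gs = G0 + 1.6 (1 + G1/VPDcan) GPP/Ca} in mol m-2 s-1.
#'
#' @param g0 residual conductance, mol m-2 s-1.
#' @param g1 slope parameter, kPa.
#' @param gpp GPP, micromol m-2 s-1.
#' @param vpdcan canopy-to-air VPD, kPa (> 0).
#' @param ca ambient CO2, micromol mol-1.
#' @param sqrt_vpd square-root VPD response variant.
#' @return mol m-2 s-1 (NA where vpdcan <= 0).
#' @export
#' @examples
#' medlyn_predict(0.01, 3, gpp = 30, vpdcan = 1, ca = 420)  # about 0.467
medlyn_predict <- function(g0, g1, gpp, vpdcan, ca = 420, sqrt_vpd = FALSE) {
  v <- if (sqrt_vpd) sqrt(vpdcan) else vpdcan
  ifelse(vpdcan > 0, g0 + 1.6 * (1 + g1 / v) * gpp / ca, NA_real_)
}

#' Scale an H2O conductance to an O3 conductance
#'
#' Multiplies by the ratio of O3 to H2O molecular diffusivities (0.61).
#'
#' @param gs_h2o conductance to water vapor (any units).
#' @param constants list from [flux_constants()].
#' @return conductance to ozone, same units.
#' @export
h2o_to_o3_conductance <- function(gs_h2o, constants = flux_constants()) {
  stopifnot(all(gs_h2o >= 0, na.rm = TRUE))
  constants$D_ratio_o3_h2o * gs_h2o
}

#' Conductance stage: PM inversion, Medlyn fits, ozone conductances
#'
#' Runs the full conductance chain on a half-hourly table that already
#' carries the deposition-stage columns (RA, RB_*, RC_O3, RHO, CP) and a
#' GPP column: surface temperature, canopy VPD, PM inversion, the
#' rain/zenith/humidity validity mask, windowed (or season-wide) Medlyn
#' fits, per-record Medlyn predictions, conversion of both estimates to O3
#' conductances, and the stomatal-to-bulk conductance ratios with the
#' closed-interval [0, 1] filter.
#'
#' @param df half-hourly table (deposition stage applied) with columns
#'   \code{TA}, \code{RH}, \code{PA}, \code{P}, \code{H}, \code{LE},
#'   \code{GPP}, \code{RA}, \code{RB_H2O}, \code{RB_HEAT}, \code{RC_O3},
#'   \code{RHO}, \code{CP}, \code{timestamp}.
#' @param site a [site_meta()] object.
#' @param rain_window_h,rh_max,sza_max filter settings, see
#'   [stomatal_validity_mask()].
#' @param window_days Medlyn window width in days (Inf = season-wide fit).
#' @param min_obs minimum observations per Medlyn window.
#' @param sqrt_vpd use the square-root VPD Medlyn variant.
#' @param constants list from [flux_constants()].
#' @return list with \code{data} (the table extended with TS, VPDCAN,
#'   GS_H2O_PM (m s-1), GS_H2O_PM_MOL, GS_H2O_MED_MOL, GS_O3_PM, GS_O3_MED
#'   (m s-1), GC_O3, RATIO_PM, RATIO_MED, VALID_MASK, REASON, RATIO_OK_*),
#'   \code{fits} (Medlyn fit table) and \code{exclusions} (named counts).
#' @export
add_conductance <- function(df, site = site_meta(), rain_window_h = 36,
                            rh_max = 80, sza_max = 85, window_days = 10,
                            min_obs = 20L, sqrt_vpd = FALSE,
                            constants = flux_constants()) {
  need <- c("TA", "RH", "PA", "P", "H", "LE", "GPP", "RA", "RB_H2O",
            "RB_HEAT", "RC_O3", "RHO", "CP", "timestamp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  gamma <- psychrometric_gamma(df$TA, df$PA, df$CP)
  er <- vapor_pressure(df$TA, df$RH)
  ts_surf <- surface_temperature(df$TA, df$H, df$RHO, df$CP,
                                 df$RA, df$RB_HEAT)
  vpdcan <- canopy_vpd(ts_surf, er)

  sol <- solar_position(df$timestamp - 900, site$latitude, site$longitude,
                        site$utc_offset)
  mask <- stomatal_validity_mask(df$timestamp, df$P, df$RH, sol$zenith,
                                 rain_window_h, rh_max, sza_max)

  pm <- pm_inversion(df$LE, vpdcan, gamma, df$RHO, df$CP, df$RA, df$RB_H2O)
  gs_pm_ms <- ifelse(mask$valid, pm$gs_ms, NA_real_)
  n_air <- molar_density_air(df$TA, df$PA, constants)
  gs_pm_mol <- gs_pm_ms * n_air

  fits <- fit_medlyn_windows(gs_pm_mol, df$GPP, vpdcan, df$timestamp,
                             ca = site$ca, window_days = window_days,
                             min_obs = min_obs, sqrt_vpd = sqrt_vpd)

  gs_med_mol <- rep(NA_real_, nrow(df))
  if (nrow(fits)) {
    tnum <- as.numeric(df$timestamp)
    for (i in seq_len(nrow(fits))) {
      if (!fits$converged[i]) next
      in_win <- tnum >= as.numeric(fits$start[i]) &
        tnum <= as.numeric(fits$end[i])
      gs_med_mol[in_win] <- medlyn_predict(fits$g0[i], fits$g1[i],
                                           df$GPP[in_win], vpdcan[in_win],
                                           site$ca, sqrt_vpd)
    }
  }
  gs_med_ms <- gs_med_mol / n_air

  gs_o3_pm <- h2o_to_o3_conductance(pmax(gs_pm_ms, 0), constants)
  gs_o3_med <- h2o_to_o3_conductance(pmax(gs_med_ms, 0), constants)
  gc_o3 <- ifelse(!is.na(df$RC_O3) & df$RC_O3 > 0, 1 / df$RC_O3, NA_real_)
  ratio_pm <- gs_o3_pm / gc_o3
  ratio_med <- ifelse(mask$valid, gs_o3_med / gc_o3, NA_real_)

  ratio_ok <- function(r) !is.na(r) & r >= 0 & r <= 1
  df$TS <- ts_surf
  df$VPDCAN <- vpdcan
  df$SZA <- sol$zenith
  df$GS_H2O_PM <- gs_pm_ms
  df$GS_H2O_PM_MOL <- gs_pm_mol
  df$GS_H2O_MED_MOL <- gs_med_mol
  df$GS_O3_PM <- ifelse(mask$valid, gs_o3_pm, NA_real_)
  df$GS_O3_MED <- ifelse(mask$valid, gs_o3_med, NA_real_)
  df$GC_O3 <- gc_o3
  df$RATIO_PM <- ifelse(ratio_ok(ratio_pm) & mask$valid, ratio_pm, NA_real_)
  df$RATIO_MED <- ifelse(ratio_ok(ratio_med), ratio_med, NA_real_)
  df$VALID_MASK <- mask$valid
  df$REASON <- mask$reason
  df$REASON[mask$valid & pm$reason != ""] <- pm$reason[mask$valid & pm$reason != ""]
  df$REASON[mask$valid & pm$reason == "" &
              !is.na(gc_o3) & !ratio_ok(ratio_pm)] <- "ratio"

  excl <- c(mask$counts,
            pm = sum(mask$valid & pm$reason != ""),
            ratio = sum(df$REASON == "ratio"))
  list(data = df, fits = fits, exclusions = excl)
}
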