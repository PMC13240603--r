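# Synthetic big-leaf world: half-hourly drivers and fluxes generated from a
# known resistance network and Medlyn conductance, so that every downstream
# stage (deposition, Penman-Monteith inversion, Medlyn fitting, dose metrics)
# can be checked against ground truth.

#' Ground-truth parameters for the synthetic world
#'
#' Bundles the parameters of the synthetic big-leaf generator. Defaults
#' describe a well-watered C4 maize canopy in a continental humid summer:
#' high light-saturated assimilation, afternoon-peaking ozone, modest
#' non-stomatal deposition, and a nighttime friction-velocity suppression of
#' measured NEE below 0.09 m s-1.
#'
#' @param g0 residual (minimum) stomatal conductance, mol m-2 s-1.
#' @param g1 Medlyn slope parameter, kPa.
#' @param gns non-stomatal ozone conductance, m s-1.
#' @param amax light-saturated gross primary productivity, micromol m-2 s-1.
#' @param alpha_q initial light-use slope of the rectangular hyperbola,
#'   micromol CO2 per J of shortwave (micromol / (W m-2) per s).
#' @param gpp_t_sens linear temperature stimulation of GPP around
#'   \code{gpp_t_ref}, per K. C4 maize photosynthesis increases toward its
#'   warm optimum, which keeps stomata open through the warm afternoon.
#' @param gpp_t_ref reference temperature for the stimulation, degrees C.
#' @param rref ecosystem respiration at 10 degrees C, micromol m-2 s-1.
#' @param e0 Lloyd-Taylor temperature sensitivity, K.
#' @param o3_base baseline ozone mixing ratio, ppb.
#' @param o3_amp amplitude of the afternoon ozone bump, ppb.
#' @param o3_peak_hour decimal hour of the ozone peak.
#' @param rain_rate expected precipitation events per day.
#' @param ustar_thresh friction velocity below which measured nighttime NEE
#'   is attenuated (weak-turbulence bias), m s-1.
#' @param noise_sd named list of noise scales: \code{flux} (relative, applied
#'   multiplicatively to H, LE, FC and the O3 flux), \code{o3} (relative, on
#'   the O3 mixing ratio), \code{temp} (additive, degrees C).
#' @param seed integer seed driving all random draws.
#' @return A list of class \code{truth_params}.
#' @export
#' @examples
#' truth_params(g1 = 3, seed = 42)
truth_params <- function(g0 = 0.02, g1 = 1.0, gns = 0.0011,
                         amax = 80, alpha_q = 0.12,
                         gpp_t_sens = 0.05, gpp_t_ref = 23,
                         rref = 2.0, e0 = 200,
                         o3_base = 22, o3_amp = 28, o3_peak_hour = 14,
                         rain_rate = 0.15, ustar_thresh = 0.09,
                         noise_sd = list(flux = 0.05, o3 = 0.03, temp = 0.2),
                         seed = 1L) {
  stopifnot(g0 >= 0, g1 >= 0, gns >= 0, amax > 0, alpha_q > 0,
            o3_base >= 0, o3_amp >= 0, rain_rate >= 0, ustar_thresh >= 0)
  ns <- utils::modifyList(list(flux = 0.05, o3 = 0.03, temp = 0.2),
                          as.list(noise_sd))
  stopifnot(all(unlist(ns) >= 0), ns$flux < 1, ns$o3 < 1)
  structure(list(g0 = g0, g1 = g1, gns = gns, amax = amax, alpha_q = alpha_q,
                 gpp_t_sens = gpp_t_sens, gpp_t_ref = gpp_t_ref,
                 rref = rref, e0 = e0, o3_base = o3_base, o3_amp = o3_amp,
                 o3_peak_hour = o3_peak_hour, rain_rate = rain_rate,
                 ustar_thresh = ustar_thresh, noise_sd = ns,
                 seed = as.integer(seed)),
            class = "truth_params")
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Generate half-hourly meteorological drivers
#'
#' Builds a deterministic (given the seed) half-hourly driver series with a
#' clear-sky shortwave sinusoid modulated by a daily cloud factor, air
#' temperature lagging radiation with an afternoon peak, humidity tied to a
#' nightly dew point, Poisson-distributed precipitation events that darken
#' the sky and saturate the air, and wind speed / friction velocity with a
#' daytime maximum.
#'
#' @param days number of days to simulate (>= 1).
#' @param params a [truth_params()] object.
#' @param site a [site_meta()] object.
#' @param start_date first day, \code{Date} or \code{"YYYY-MM-DD"}.
#' @return data.frame with one row per half hour (timestamps are
#'   end-of-interval local standard time): \code{timestamp}, \code{SW_IN}
#'   (W m-2), \code{TA} (degC), \code{RH} (percent), \code{PA} (kPa),
#'   \code{P} (mm), \code{WS} (m s-1), \code{USTAR} (m s-1), and the solar
#'   elevation at the interval midpoint (\code{SOLAR_ELEV}, degrees).
#' @export
gen_meteorology <- function(days, params = truth_params(),
                            site = site_meta(), start_date = "2023-07-01") {
  if (!is.numeric(days) || length(days) != 1 || days < 1)
    stop("'days' must be a positive number of days")
  days <- as.integer(days)
  n <- days * 48L
  t0 <- as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC")
  ts_end <- t0 + seq_len(n) * 1800
  ts_mid <- ts_end - 900
  day_idx <- rep(seq_len(days), each = 48L)
  hour <- (as.numeric(ts_mid - t0, units = "hours")) %% 24

  sol <- solar_position(ts_mid, site$latitude, site$longitude, site$utc_offset)
  sw_pot <- 1000 * pmax(0, sin(pmax(0, sol$elevation) * pi / 180))

  with_seed(params$seed, {
    cloud <- stats::runif(days, 0.55, 1.0)[day_idx]

    # precipitation: Poisson number of events, each 1-3 half-hours long
    n_events <- stats::rpois(1, params$rain_rate * days)
    precip <- numeric(n)
    if (n_events > 0) {
      starts <- sample.int(n, n_events, replace = TRUE)
      for (s in starts) {
        len <- sample(1:3, 1)
        idx <- s:min(n, s + len - 1)
        precip[idx] <- precip[idx] + stats::rexp(length(idx), rate = 0.5)
      }
    }
    raining <- precip > 0
    cloud[raining] <- pmin(cloud[raining], 0.25)
    sw_in <- sw_pot * cloud

    # temperature: daily mean anomaly + diurnal cycle peaking mid-afternoon
    t_mean <- 23 + stats::rnorm(days, 0, 1.5)[day_idx]
    t_amp <- 5.5
    ta <- t_mean + t_amp * cos(2 * pi * (hour - 14.5) / 24)
    ta <- ta - 2 * raining

    # humidity anchored to a nightly dew point near the daily minimum
    td <- (t_mean - t_amp) + stats::runif(days, 0, 1.5)[day_idx]
    rh <- 100 * saturation_vapor_pressure(td) / saturation_vapor_pressure(ta)
    rh[raining] <- 97
    rh <- pmin(100, pmax(20, rh))

    pa <- 101.0 + stats::rnorm(days, 0, 0.15)[day_idx]

    # wind: daytime enhancement plus lognormal variability
    ws <- (0.7 + 2.3 * sw_pot / 1000) *
      exp(stats::rnorm(n, 0, 0.35))
    ws <- pmax(0.2, ws)
    ustar <- 0.15 * ws * exp(stats::rnorm(n, 0, 0.10))

    data.frame(timestamp = ts_end, SW_IN = sw_in, TA = ta, RH = rh, PA = pa,
               P = precip, WS = ws, USTAR = ustar,
               SOLAR_ELEV = sol$elevation)
  })
}

# Lloyd-Taylor respiration, micromol m-2 s-1.
#' Lloyd-Taylor ecosystem respiration
#'
#' \code{Reco = Rref exp(E0 (1/(283.15 - 227.13) - 1/(T_K - 227.13)))}.
#'
#' @param tair air temperature, degrees C.
#' @param rref base respiration at 10 degrees C, micromol m-2 s-1.
#' @param e0 temperature sensitivity, K.
#' @return micromol m-2 s-1.
#' @export
lloyd_taylor <- function(tair, rref, e0) {
  rref * exp(e0 * (1 / (283.15 - 227.13) - 1 / (tair + 273.15 - 227.13)))
}

#' Rectangular-hyperbola light response
#'
#' \code{GPP = amax alpha_q SWin / (amax + alpha_q SWin)}.
#'
#' @param swin incoming shortwave, W m-2.
#' @param amax light-saturated GPP, micromol m-2 s-1.
#' @param alpha_q initial slope, micromol per (W m-2) per s.
#' @return micromol m-2 s-1.
#' @export
light_response <- function(swin, amax, alpha_q) {
  amax * alpha_q * swin / (amax + alpha_q * swin)
}

#' Forward big-leaf model: half-hourly observations plus hidden truth
#'
#' Runs the forward resistance-network model on a driver series. Stomatal
#' conductance follows the Medlyn form driven by the light-response GPP and
#' the canopy-to-air vapor pressure deficit; latent heat comes from the
#' evaporation-resistance (Penman-Monteith) formulation, sensible heat from
#' the available-energy balance, and the surface temperature / canopy VPD
#' loop is solved to a fixed point per record so that inverting the same
#' equations recovers the truth exactly in the noiseless case. The ozone
#' deposition velocity combines the scaled stomatal conductance with the
#' prescribed non-stomatal conductance through the series resistance network.
#'
#' Measured nighttime NEE is attenuated linearly below the friction-velocity
#' threshold \code{params$ustar_thresh}, mimicking the weak-turbulence bias
#' that u*-filtering is designed to remove.
#'
#' @param meteo output of [gen_meteorology()].
#' @param params a [truth_params()] object.
#' @param site a [site_meta()] object.
#' @return list with \code{obs} (the observation table: meteorology plus
#'   noisy H, LE, FC, FO3, O3 columns) and \code{truth} (sidecar table of
#'   noise-free hidden states: GPP, RECO, NEE, GS_H2O_MOL, GS_O3, GC_O3,
#'   RC_O3, VD, FO3, VPDCAN, TS, RATIO_STOM, plus RA and boundary-layer
#'   resistances).
#' @export
gen_halfhourly_truth <- function(meteo, params = truth_params(),
                                 site = site_meta()) {
  stopifnot(is.data.frame(meteo), nrow(meteo) > 0)
  cst <- flux_constants()
  n <- nrow(meteo)

  ra <- aerodynamic_resistance(meteo$WS, meteo$USTAR)
  rb_o3 <- quasilaminar_resistance(meteo$USTAR, "O3", cst)
  rb_h2o <- quasilaminar_resistance(meteo$USTAR, "H2O", cst)
  rb_heat <- quasilaminar_resistance(meteo$USTAR, "heat", cst)

  rho <- air_density(meteo$TA, meteo$RH, meteo$PA, cst)
  cp <- specific_heat_air(meteo$TA, meteo$RH, meteo$PA, cst)
  lambda_v <- latent_heat_vaporization(meteo$TA)
  gamma <- psychrometric_gamma(meteo$TA, meteo$PA, cp)
  er <- vapor_pressure(meteo$TA, meteo$RH)
  n_air <- molar_density_air(meteo$TA, meteo$PA, cst)

  gpp <- light_response(meteo$SW_IN, params$amax, params$alpha_q) *
    pmax(0.4, 1 + params$gpp_t_sens * (meteo$TA - params$gpp_t_ref))
  reco <- lloyd_taylor(meteo$TA, params$rref, params$e0)
  avail_energy <- 0.60 * meteo$SW_IN  # net radiation minus storage, crude

  # fixed point in H: H -> Ts -> VPDcan -> Gs -> lambdaE -> H = A - lambdaE
  medlyn_gs <- function(vpdcan) {
    v <- pmax(vpdcan, 1e-3)
    gs <- params$g0 + 1.6 * (1 + params$g1 / v) * gpp / site$ca
    ifelse(vpdcan > 0, gs, params$g0)
  }
  h <- rep(0, n)
  for (i in seq_len(200)) {
    ts_surf <- meteo$TA + h * (ra + rb_heat) / (rho * cp)
    vpdcan <- saturation_vapor_pressure(ts_surf) - er
    gs_mol <- medlyn_gs(vpdcan)
    rc_h2o <- n_air / gs_mol  # 1 / (gs in m s-1)
    le <- rho * cp * vpdcan / (gamma * (ra + rb_h2o + rc_h2o))
    h_new <- avail_energy - le
    delta <- max(abs(h_new - h))
    h <- 0.5 * h + 0.5 * h_new
    if (delta < 1e-12) break
  }
  # final, internally consistent states
  ts_surf <- meteo$TA + h * (ra + rb_heat) / (rho * cp)
  vpdcan <- saturation_vapor_pressure(ts_surf) - er
  gs_mol <- medlyn_gs(vpdcan)
  gs_h2o_ms <- gs_mol / n_air
  rc_h2o <- 1 / gs_h2o_ms
  le <- rho * cp * vpdcan / (gamma * (ra + rb_h2o + rc_h2o))

  # ozone pathway
  gs_o3 <- cst$D_ratio_o3_h2o * gs_h2o_ms
  gc_o3 <- gs_o3 + params$gns
  rc_o3 <- 1 / gc_o3
  vd <- 1 / (ra + rb_o3 + rc_o3)

  hour <- as.numeric(format(meteo$timestamp - 900, "%H", tz = "UTC")) +
    as.numeric(format(meteo$timestamp - 900, "%M", tz = "UTC")) / 60
  o3_ppb_true <- pmax(0, params$o3_base +
    params$o3_amp * exp(-(hour - params$o3_peak_hour)^2 / (2 * 3^2)))
  conc <- ppb_to_molar_density(o3_ppb_true, meteo$TA, meteo$PA, cst)
  fo3 <- vd * conc  # nmol m-2 s-1, deposition positive

  nee <- reco - gpp  # micrometeorological sign: negative = uptake
  night <- meteo$SOLAR_ELEV <= 0

  truth <- data.frame(
    timestamp = meteo$timestamp,
    GPP = gpp, RECO = reco, NEE = nee,
    GS_H2O_MOL = gs_mol, GS_O3 = gs_o3, GC_O3 = gc_o3, RC_O3 = rc_o3,
    VD = vd, FO3 = fo3, O3 = o3_ppb_true,
    VPDCAN = vpdcan, TS = ts_surf, H = h, LE = le,
    RA = ra, RB_O3 = rb_o3, RB_H2O = rb_h2o, RB_HEAT = rb_heat,
    RATIO_STOM = gs_o3 / gc_o3, NIGHT = night
  )

  ns <- params$noise_sd
  obs <- with_seed(params$seed + 1L, {
    mult <- function(x, sd) x * (1 + stats::rnorm(n, 0, sd))
    nee_meas <- nee
    low <- night & meteo$USTAR < params$ustar_thresh
    nee_meas[low] <- nee_meas[low] *
      (meteo$USTAR[low] / params$ustar_thresh)
    data.frame(
      timestamp = meteo$timestamp,
      SW_IN = meteo$SW_IN,
      TA = meteo$TA + stats::rnorm(n, 0, ns$temp),
      RH = meteo$RH, PA = meteo$PA, P = meteo$P,
      WS = meteo$WS, USTAR = meteo$USTAR,
      H = mult(h, ns$flux),
      LE = mult(le, ns$flux),
      FC = mult(nee_meas, ns$flux),
      FO3 = mult(fo3, ns$flux),
      O3 = pmax(0, mult(o3_ppb_true, ns$o3))
    )
  })
  list(obs = obs, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper chaining [gen_meteorology()] and
#' [gen_halfhourly_truth()].
#'
#' @inheritParams gen_meteorology
#' @param site a [site_meta()] object.
#' @return list with \code{obs}, \code{truth}, \code{params}, \code{site}.
#' @export
#' @examples
#' world <- simulate_dataset(3, truth_params(seed = 7))
#' head(world$obs)
simulate_dataset <- function(days, params = truth_params(),
                             site = site_meta(), start_date = "2023-07-01") {
  meteo <- gen_meteorology(days, params, site, start_date)
  out <- gen_halfhourly_truth(meteo, params, site)
  out$params <- params
  out$site <- site
  out
}

#' Generate a correlated-turbulence high-frequency block
#'
#' 30 minutes of 10 Hz pseudo-turbulence: jointly Gaussian vertical wind and
#' scalar channels with prescribed population covariances, optionally tilted
#' in the u-w plane (simulating sonic anemometer misalignment), with
#' injected spikes and missing samples.
#'
#' @param cov_ws population covariance between w and the ozone molar density
#'   channel, (m s-1)(nmol m-3).
#' @param tilt_deg pitch misalignment, degrees (|tilt| < 30).
#' @param spike_frac fraction of samples turned into spikes, in [0, 0.5].
#' @param missing_frac fraction of samples set missing, in [0, 0.5].
#' @param seed integer seed.
#' @param n number of samples (default 18000 = 30 min at 10 Hz).
#' @param mean_u mean streamwise wind, m s-1.
#' @param cov_uw population covariance of u and w (momentum flux), m2 s-2;
#'   the default gives \code{sigma_w / ustar} near the neutral surface-layer
#'   value of 1.3.
#' @param cov_wT population covariance of w and sonic temperature, K m s-1.
#' @return data.frame with columns \code{t} (s), \code{u}, \code{v},
#'   \code{w} (m s-1), \code{Ts} (degC), \code{c_co2}, \code{c_h2o}
#'   (micromol m-3) and \code{c_o3} (nmol m-3).
#' @export
gen_highfreq_block <- function(cov_ws, tilt_deg = 0, spike_frac = 0,
                               missing_frac = 0, seed = 1L, n = 18000L,
                               mean_u = 2, cov_uw = -0.148, cov_wT = 0.05) {
  if (abs(tilt_deg) >= 30) stop("|tilt_deg| must be < 30 degrees")
  if (spike_frac < 0 || spike_frac > 0.5) stop("spike_frac must be in [0, 0.5]")
  if (missing_frac < 0 || missing_frac > 0.5) stop("missing_frac must be in [0, 0.5]")
  sd_w <- 0.5
  with_seed(seed, {
    zw <- stats::rnorm(n)
    w <- sd_w * zw
    corr_with_w <- function(cov, sd_resid, mean = 0) {
      mean + (cov / sd_w) * zw + sd_resid * stats::rnorm(n)
    }
    u <- corr_with_w(cov_uw, 0.6, mean_u)
    v <- 0.4 * stats::rnorm(n)
    ts <- corr_with_w(cov_wT, 0.3, 25)
    c_o3 <- corr_with_w(cov_ws, 2.5, 1800)
    c_co2 <- corr_with_w(-0.5 * cov_ws, 2.0, 16000)
    c_h2o <- corr_with_w(0.8 * cov_ws, 2.5, 7e5)

    if (tilt_deg != 0) {  # instrument tilt: rotate the streamline frame away
      a <- tilt_deg * pi / 180
      u_m <- u * cos(a) - w * sin(a)
      w_m <- u * sin(a) + w * cos(a)
      u <- u_m; w <- w_m
    }
    if (spike_frac > 0) {
      idx <- sample.int(n, max(1L, floor(spike_frac * n)))
      w[idx] <- w[idx] + sample(c(-1, 1), length(idx), TRUE) * 15 * sd_w
      c_o3[idx] <- c_o3[idx] + sample(c(-1, 1), length(idx), TRUE) * 40
    }
    out <- data.frame(t = (seq_len(n) - 1) / 10, u = u, v = v, w = w,
                      Ts = ts, c_co2 = c_co2, c_h2o = c_h2o, c_o3 = c_o3)
    if (missing_frac > 0) {
      idx <- sample.int(n, floor(missing_frac * n))
      for (col in c("u", "v", "w", "Ts", "c_co2", "c_h2o", "c_o3"))
        out[[col]][idx] <- NA_real_
    }
    out
  })
}
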