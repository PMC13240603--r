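# Resistance-network ozone deposition: unit conversion, deposition velocity,
# aerodynamic / quasi-laminar / surface resistances, and Obukhov stability.

#' Convert a mixing ratio in ppb to molar density
#'
#' Ideal-gas conversion so that flux / density yields a velocity in m s-1.
#'
#' @param x_ppb mixing ratio, ppb (nmol mol-1).
#' @param temp air temperature, degrees C.
#' @param pressure air pressure, kPa.
#' @param constants list from [flux_constants()].
#' @return molar density, nmol m-3.
#' @export
#' @examples
#' ppb_to_molar_density(40, 25, 101.325)  # about 1635 nmol m-3
ppb_to_molar_density <- function(x_ppb, temp, pressure,
                                 constants = flux_constants()) {
  stopifnot(all(pressure > 0, na.rm = TRUE), all(temp > -100, na.rm = TRUE))
  x_ppb * pressure * 1000 / (constants$R_gas * (temp + 273.15))
}

#' Ozone deposition velocity
#'
#' \code{Vd = Flux / [O3]} with the surface concentration taken as zero.
#' A negative flux (emission-like) gives a negative velocity, which callers
#' flag rather than silently drop.
#'
#' @param flux_o3 ozone flux toward the surface, nmol m-2 s-1.
#' @param conc ozone molar density at measurement height, nmol m-3.
#' @return m s-1.
#' @export
deposition_velocity <- function(flux_o3, conc) {
  if (any(conc <= 0, na.rm = TRUE)) stop("ozone concentration must be > 0")
  flux_o3 / conc
}

#' Aerodynamic resistance
#'
#' \code{Ra = u / ustar^2}, no stability correction.
#'
#' @param u wind speed at measurement height, m s-1.
#' @param ustar friction velocity, m s-1.
#' @return s m-1.
#' @export
#' @examples
#' aerodynamic_resistance(2, 0.2)  # 50 s m-1
aerodynamic_resistance <- function(u, ustar) {
  if (any(ustar <= 0, na.rm = TRUE)) stop("ustar must be > 0")
  u / ustar^2
}

#' Quasi-laminar boundary layer resistance
#'
#' \code{Rb = 2 / (k ustar) (Sc/Pr)^(2/3)} with the Schmidt-to-Prandtl ratio
#' expressed as thermal diffusivity over the gas diffusivity; for heat the
#' ratio is 1.
#'
#' @param ustar friction velocity, m s-1.
#' @param gas one of \code{"O3"}, \code{"H2O"}, \code{"heat"}.
#' @param constants list from [flux_constants()].
#' @return s m-1.
#' @export
#' @examples
#' quasilaminar_resistance(0.4, "O3")  # about 15.9 s m-1
quasilaminar_resistance <- function(ustar, gas = c("O3", "H2O", "heat"),
                                    constants = flux_constants()) {
  gas <- match.arg(gas)
  if (any(ustar <= 0, na.rm = TRUE)) stop("ustar must be > 0")
  ratio <- switch(gas,
                  O3 = constants$kappa_heat / constants$D_o3,
                  H2O = constants$kappa_heat / constants$D_h2o,
                  heat = 1)
  2 / (constants$k * ustar) * ratio^(2 / 3)
}

#' Bulk surface resistance from the series resistance network
#'
#' Inverts \code{Vd = (Ra + Rb + Rc)^-1}: \code{Rc = 1/Vd - Ra - Rb}.
#' Negative results (1/Vd smaller than the transport resistances) are
#' returned as-is; downstream code flags and excludes them.
#'
#' @param vd deposition velocity, m s-1 (must be > 0).
#' @param ra aerodynamic resistance, s m-1.
#' @param rb_o3 quasi-laminar resistance to O3, s m-1.
#' @return s m-1.
#' @export
surface_resistance <- function(vd, ra, rb_o3) {
  if (any(vd <= 0, na.rm = TRUE)) stop("vd must be > 0")
  1 / vd - ra - rb_o3
}

#' Obukhov length and stability parameter
#'
#' \code{L = -rho cp ustar^3 T_K / (k g H)} and \code{zeta = (r - d) / L}
#' with the displacement height \code{d} a fixed fraction of canopy height.
#' \code{H = 0} gives \code{zeta = 0} (neutral) by convention.
#'
#' @param ustar friction velocity, m s-1.
#' @param h sensible heat flux, W m-2.
#' @param tair air temperature, degrees C.
#' @param rho air density, kg m-3.
#' @param cp specific heat of air, J kg-1 K-1.
#' @param site a [site_meta()] object.
#' @param constants list from [flux_constants()].
#' @return data.frame with columns \code{L} (m) and \code{zeta}.
#' @export
obukhov_stability <- function(ustar, h, tair, rho, cp = flux_constants()$cp_dry,
                              site = site_meta(),
                              constants = flux_constants()) {
  t_k <- tair + 273.15
  L <- ifelse(h == 0, Inf,
              -rho * cp * ustar^3 * t_k / (constants$k * constants$g * h))
  d <- constants$disp_frac * site$canopy_height
  zeta <- ifelse(is.finite(L), (site$measurement_height - d) / L, 0)
  data.frame(L = L, zeta = zeta)
}

#' Add deposition-stage columns to a half-hourly table
#'
#' Computes the ozone molar density, deposition velocity and the resistance
#' decomposition (Ra, Rb, Rc) plus the stability parameter for each half
#' hour. Records with non-positive ustar, wind speed or ozone concentration,
#' or with a negative derived surface resistance, are flagged.
#'
#' @param df half-hourly table with columns \code{WS}, \code{USTAR},
#'   \code{TA}, \code{RH}, \code{PA}, \code{H}, \code{FO3}, \code{O3}.
#' @param site a [site_meta()] object.
#' @param constants list from [flux_constants()].
#' @return \code{df} with added columns \code{O3_DENS} (nmol m-3),
#'   \code{VD_O3} (m s-1), \code{RA}, \code{RB_O3}, \code{RB_H2O},
#'   \code{RB_HEAT}, \code{RC_O3} (s m-1), \code{L}, \code{ZETA},
#'   \code{RHO}, \code{CP}, and \code{FLAG_DEPO} (0 ok; 1 bad inputs;
#'   2 negative Vd; 3 negative Rc).
#' @export
add_deposition <- function(df, site = site_meta(),
                           constants = flux_constants()) {
  need <- c("WS", "USTAR", "TA", "RH", "PA", "H", "FO3", "O3")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  ok_in <- !is.na(df$USTAR) & df$USTAR > 0 & !is.na(df$WS) &
    !is.na(df$O3) & df$O3 > 0 & !is.na(df$FO3) & !is.na(df$TA) &
    !is.na(df$PA)

  n <- nrow(df)
  dens <- vd <- ra <- rb_o3 <- rb_h2o <- rb_heat <- rc <- rep(NA_real_, n)
  dens[ok_in] <- ppb_to_molar_density(df$O3[ok_in], df$TA[ok_in],
                                      df$PA[ok_in], constants)
  vd[ok_in] <- deposition_velocity(df$FO3[ok_in], dens[ok_in])
  ra[ok_in] <- aerodynamic_resistance(df$WS[ok_in], df$USTAR[ok_in])
  rb_o3[ok_in] <- quasilaminar_resistance(df$USTAR[ok_in], "O3", constants)
  rb_h2o[ok_in] <- quasilaminar_resistance(df$USTAR[ok_in], "H2O", constants)
  rb_heat[ok_in] <- quasilaminar_resistance(df$USTAR[ok_in], "heat", constants)
  pos <- ok_in & vd > 0
  rc[pos] <- surface_resistance(vd[pos], ra[pos], rb_o3[pos])

  rho <- air_density(df$TA, df$RH, df$PA, constants)
  cp <- specific_heat_air(df$TA, df$RH, df$PA, constants)
  stab <- obukhov_stability(df$USTAR, df$H, df$TA, rho, cp, site, constants)

  flag <- integer(n)
  flag[!ok_in] <- 1L
  flag[ok_in & !(vd > 0)] <- 2L
  flag[pos & rc <= 0] <- 3L

  df$O3_DENS <- dens
  df$VD_O3 <- vd
  df$RA <- ra
  df$RB_O3 <- rb_o3
  df$RB_H2O <- rb_h2o
  df$RB_HEAT <- rb_heat
  df$RC_O3 <- ifelse(flag == 0L, rc, NA_real_)
  df$L <- stab$L
  df$ZETA <- stab$zeta
  df$RHO <- rho
  df$CP <- cp
  df$FLAG_DEPO <- flag
  df
}
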