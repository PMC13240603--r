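#' Physical constants used by the resistance network
#'
#' Returns the set of physical constants used throughout the deposition and
#' conductance calculations. Any entry can be overridden, e.g. to explore the
#' sensitivity of the quasi-laminar resistance to the assumed diffusivities.
#'
#' @param ... named overrides for individual constants.
#'
#' @return A named list with elements:
#' \describe{
#'   \item{k}{von Karman constant (0.4, dimensionless).}
#'   \item{kappa_heat}{thermal diffusivity of air, cm2 s-1.}
#'   \item{D_o3}{molecular diffusivity of O3 in air, cm2 s-1.}
#'   \item{D_h2o}{molecular diffusivity of H2O in air, cm2 s-1.}
#'   \item{D_ratio_o3_h2o}{ratio of O3 to H2O diffusivity used to scale
#'     stomatal conductance between the two gases (0.61).}
#'   \item{g}{gravitational acceleration, m s-2.}
#'   \item{R_gas}{universal gas constant, J mol-1 K-1.}
#'   \item{M_h2o}{molar mass of water, kg mol-1.}
#'   \item{M_dry}{molar mass of dry air, kg mol-1.}
#'   \item{cp_dry}{specific heat of dry air at constant pressure, J kg-1 K-1.}
#'   \item{disp_frac}{zero-plane displacement as a fraction of canopy height.}
#' }
#' @export
#' @examples
#' cst <- flux_constants()
#' cst$k
#' flux_constants(D_o3 = 0.15)$D_o3
flux_constants <- function(...) {
  cst <- list(
    k = 0.4,
    kappa_heat = 0.2,
    D_o3 = 0.14,
    D_h2o = 0.249,
    D_ratio_o3_h2o = 0.61,
    g = 9.81,
    R_gas = 8.314,
    M_h2o = 0.01802,
    M_dry = 0.028964,
    cp_dry = 1004.7,
    disp_frac = 0.67
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cst))
    if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
    cst[names(dots)] <- dots
  }
  stopifnot(all(unlist(cst) > 0), cst$D_ratio_o3_h2o < 1)
  cst
}

#' Saturation vapor pressure (Magnus form)
#'
#' @param temp air or surface temperature, degrees C.
#' @return Saturation vapor pressure, kPa.
#' @export
#' @examples
#' saturation_vapor_pressure(0)   # 0.6108 kPa
#' saturation_vapor_pressure(25)
saturation_vapor_pressure <- function(temp) {
  stopifnot(all(temp > -60, na.rm = TRUE))
  0.6108 * exp(17.27 * temp / (temp + 237.3))
}

#' Actual vapor pressure from relative humidity
#'
#' @param temp air temperature, degrees C.
#' @param rh relative humidity, percent (0-100).
#' @return Vapor pressure, kPa.
#' @export
vapor_pressure <- function(temp, rh) {
  saturation_vapor_pressure(temp) * rh / 100
}

#' Latent heat of vaporization of water
#'
#' Linear temperature dependence adequate over the ambient range.
#'
#' @param temp air temperature, degrees C.
#' @return J kg-1.
#' @export
latent_heat_vaporization <- function(temp) {
  (2.501 - 0.00237 * temp) * 1e6
}

#' Moist air density
#'
#' Ideal-gas density of moist air from temperature, humidity and pressure,
#' treating dry air and water vapor as partial pressures.
#'
#' @param temp air temperature, degrees C.
#' @param rh relative humidity, percent.
#' @param pressure air pressure, kPa.
#' @param constants list from [flux_constants()].
#' @return kg m-3.
#' @export
air_density <- function(temp, rh, pressure, constants = flux_constants()) {
  t_k <- temp + 273.15
  e <- vapor_pressure(temp, rh)           # kPa
  pd <- (pressure - e) * 1000             # Pa, dry partial pressure
  (pd * constants$M_dry + e * 1000 * constants$M_h2o) / (constants$R_gas * t_k)
}

#' Specific heat of moist air
#'
#' @inheritParams air_density
#' @return J kg-1 K-1.
#' @export
specific_heat_air <- function(temp, rh, pressure, constants = flux_constants()) {
  e <- vapor_pressure(temp, rh)
  q <- 0.622 * e / (pressure - 0.378 * e)  # specific humidity, kg kg-1
  constants$cp_dry * (1 + 0.84 * q)
}

#' Psychrometric constant
#'
#' gamma = cp P / (0.622 lambda_v).
#'
#' @param temp air temperature, degrees C.
#' @param pressure air pressure, kPa.
#' @param cp specific heat of air, J kg-1 K-1.
#' @return kPa K-1.
#' @export
psychrometric_gamma <- function(temp, pressure, cp = flux_constants()$cp_dry) {
  cp * pressure / (0.622 * latent_heat_vaporization(temp))
}

#' Molar density of air
#'
#' Used to convert conductances between m s-1 and mol m-2 s-1.
#'
#' @param temp air temperature, degrees C.
#' @param pressure air pressure, kPa.
#' @param constants list from [flux_constants()].
#' @return mol m-3.
#' @export
#' @examples
#' molar_density_air(25, 101.325)  # about 40.9 mol m-3
molar_density_air <- function(temp, pressure, constants = flux_constants()) {
  pressure * 1000 / (constants$R_gas * (temp + 273.15))
}
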