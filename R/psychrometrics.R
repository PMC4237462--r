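#' Saturation vapour pressure (Tetens form)
#'
#' Saturation vapour pressure of water over a flat surface, from the
#' exponential (Tetens-form) curve used throughout agro-meteorology.
#'
#' @param t Air (or leaf) temperature, degrees C.
#' @return Saturation vapour pressure, kPa.
#' @examples
#' svp(0)   # 0.6108 kPa
#' svp(20)  # ~2.34 kPa
#' @export
svp <- function(t) {
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Slope of the saturation vapour pressure curve
#'
#' @param t Temperature, degrees C.
#' @return Slope, kPa per degree C.
#' @export
svp_slope <- function(t) {
  4098 * svp(t) / (t + 237.3)^2
}

#' Atmospheric pressure from altitude
#'
#' Standard-atmosphere pressure profile.
#'
#' @param altitude Elevation above sea level, m.
#' @return Pressure, kPa.
#' @export
atmospheric_pressure <- function(altitude) {
  101.3 * ((293 - 0.0065 * altitude) / 293)^5.26
}

#' Latent heat of vaporization of water
#'
#' @param t Temperature, degrees C.
#' @return Latent heat, MJ kg-1.
#' @export
latent_heat <- function(t) {
  2.501 - 2.361e-3 * t
}

#' Psychrometric state of moist air
#'
#' Bundles the vapour-pressure quantities used by both the
#' evapotranspiration and leaf energy-balance calculations: saturation and
#' actual vapour pressure, the slope of the saturation curve, the
#' psychrometric constant at the site pressure, and the latent heat of
#' vaporization.
#'
#' @param t Air temperature, degrees C. Must lie in (-20, 60).
#' @param rh Relative humidity, percent, in \[0, 100].
#' @param altitude Site elevation, m (default 0).
#' @return A tibble with one row per input element and columns `e_s`, `e_a`
#'   (kPa), `delta` (kPa degC-1), `gamma` (kPa degC-1), `lambda_v`
#'   (MJ kg-1) and `P_atm` (kPa).
#' @examples
#' psychrometrics(20, 50)
#' @export
psychrometrics <- function(t, rh, altitude = 0) {
  if (any(!is.finite(t)) || any(t <= -20) || any(t >= 60)) {
    abort("`t` must be finite and in (-20, 60) degrees C.")
  }
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 100)) {
    abort("`rh` must lie in [0, 100] percent.")
  }
  e_s <- svp(t)
  p <- atmospheric_pressure(altitude)
  tibble(
    e_s = e_s,
    e_a = e_s * rh / 100,
    delta = svp_slope(t),
    gamma = 0.000665 * p,
    lambda_v = latent_heat(t),
    P_atm = p
  )
}

#' Convert photosynthetic photon flux density to shortwave irradiance
#'
#' The weather station logs PPFD only. Global shortwave irradiance is
#' recovered by assuming 2.1 umol photons per J of PAR and a PAR fraction
#' of 0.5 of total shortwave, i.e. SW = PPFD / 2.1 W m-2. This single
#' conversion is the one source of truth for both the reference
#' evapotranspiration and the leaf energy-balance radiation terms.
#'
#' @param ppfd Photosynthetic photon flux density, umol m-2 s-1.
#' @return Global shortwave irradiance, W m-2.
#' @export
ppfd_to_shortwave <- function(ppfd) {
  if (any(ppfd < 0, na.rm = TRUE)) abort("`ppfd` must be >= 0.")
  ppfd / 2.1
}

# Stefan-Boltzmann constant, W m-2 K-4
SIGMA_SB <- 5.670374e-8

# specific heat of air, J mol-1 K-1
CP_MOLAR <- 29.3

#' Clear-sky atmospheric emissivity
#'
#' Brutsaert-type clear-sky emissivity from near-surface vapour pressure
#' and air temperature, used for the incoming longwave flux from the sky.
#'
#' @param e_a Actual vapour pressure, kPa.
#' @param t_air Air temperature, degrees C.
#' @return Dimensionless emissivity in (0, 1].
#' @export
sky_emissivity <- function(e_a, t_air) {
  t_k <- t_air + 273.15
  pmin(1, 1.24 * (10 * e_a / t_k)^(1 / 7))
}
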