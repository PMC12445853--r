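## Temperature responses and unit conversions shared by all modules.

.R_GAS <- 8.314          # J mol-1 K-1
.T25_K <- 298.15
.P_STD <- 101325         # Pa

arrhenius <- function(ea, temp_c) {
  tk <- temp_c + 273.15
  exp(ea * (tk - .T25_K) / (.T25_K * .R_GAS * tk))
}

check_temp <- function(temp_c, lo = -30, hi = 60) {
  if (!is.numeric(temp_c) || any(!is.finite(temp_c)))
    stop("temp_c must be finite numeric", call. = FALSE)
  if (any(temp_c < lo | temp_c > hi))
    stop(sprintf("temp_c out of validated range [%g, %g] degC", lo, hi), call. = FALSE)
  invisible(temp_c)
}

#' CO2 compensation point without dark respiration
#'
#' \eqn{\Gamma^*} at the given temperature and pressure, from the Bernacchi
#' Arrhenius response around its 25 degC reference value, scaled linearly
#' with atmospheric pressure (the reference is a mole-fraction constant).
#'
#' @param temp_c Leaf temperature, degC (validated to [-30, 60]).
#' @param patm Atmospheric pressure, Pa.
#' @param constants A [photo_constants()] object.
#' @return \eqn{\Gamma^*} in Pa.
#' @examples
#' gamma_star(25)            # 4.332 Pa, the reference value
#' gamma_star(35) > gamma_star(15)
#' @export
gamma_star <- function(temp_c, patm = .P_STD, constants = photo_constants()) {
  check_temp(temp_c)
  constants$gamma_star25 * (patm / .P_STD) * arrhenius(constants$ea_gamma_star, temp_c)
}

#' Effective Michaelis-Menten coefficient of Rubisco
#'
#' \eqn{K = K_c (1 + pO_2 / K_o)}: the CO2 Michaelis constant inflated by
#' competitive O2 binding at the ambient O2 partial pressure
#' (\code{o2_frac * patm}).
#'
#' @inheritParams gamma_star
#' @return K in Pa. Always exceeds \eqn{K_c} at the same temperature.
#' @examples
#' michaelis_k(25)  # about 70.8 Pa
#' @export
michaelis_k <- function(temp_c, patm = .P_STD, constants = photo_constants()) {
  check_temp(temp_c)
  kc <- constants$kc25 * (patm / .P_STD) * arrhenius(constants$ea_kc, temp_c)
  ko <- constants$ko25 * (patm / .P_STD) * arrhenius(constants$ea_ko, temp_c)
  kc * (1 + constants$o2_frac * patm / ko)
}

#' Viscosity of water relative to 25 degC
#'
#' \eqn{\eta^*}, the ratio of dynamic water viscosity at the given
#' temperature to its value at 25 degC, from the Vogel closed-form
#' correlation \eqn{\ln \eta = -3.7188 + 578.919 / (T_K - 137.546)}.
#' Enters the least-cost chi through the transpiration cost term.
#'
#' @param temp_c Water (leaf) temperature, degC; valid on (0, 100).
#' @return Dimensionless ratio; 1 at 25 degC, above 1 when colder.
#' @examples
#' viscosity_ratio(25)  # exactly 1
#' viscosity_ratio(10)  # > 1: colder water is more viscous
#' @export
viscosity_ratio <- function(temp_c) {
  if (!is.numeric(temp_c) || any(!is.finite(temp_c)) ||
      any(temp_c <= 0 | temp_c >= 100))
    stop("temp_c must lie in (0, 100) degC for the liquid-water viscosity correlation",
         call. = FALSE)
  visc <- function(tc) exp(-3.7188 + 578.919 / ((tc + 273.15) - 137.546))
  visc(temp_c) / visc(25)
}

#' Convert a CO2 mole fraction to a partial pressure
#'
#' @param ca_ppm Mole fraction, umol mol-1.
#' @param patm Atmospheric pressure, Pa.
#' @return Partial pressure, Pa (\code{ca_ppm * 1e-6 * patm}).
#' @examples
#' ppm_to_pa(400)  # 40.53 Pa at standard pressure
#' @export
ppm_to_pa <- function(ca_ppm, patm = .P_STD) {
  if (any(ca_ppm < 0) || any(patm <= 0))
    stop("ca_ppm must be >= 0 and patm > 0", call. = FALSE)
  ca_ppm * 1e-6 * patm
}

#' Convert a CO2 partial pressure to a mole fraction
#'
#' Inverse of [ppm_to_pa()].
#' @param ca_pa Partial pressure, Pa.
#' @param patm Atmospheric pressure, Pa.
#' @return Mole fraction, umol mol-1.
#' @export
pa_to_ppm <- function(ca_pa, patm = .P_STD) {
  if (any(ca_pa < 0) || any(patm <= 0))
    stop("ca_pa must be >= 0 and patm > 0", call. = FALSE)
  ca_pa / patm * 1e6
}
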