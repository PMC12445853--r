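#' Physiological constants for the leaf gas-exchange model
#'
#' Bundles every physiological constant used by the photosynthesis, optimality
#' and timescale-engine functions, with defaults that represent a typical
#' unstressed C3 leaf. All gas-exchange arithmetic is done in partial
#' pressures (Pa); mole fractions (ppm) appear only at the interface.
#'
#' Temperature responses of \eqn{\Gamma^*}, \eqn{K_c} and \eqn{K_o} follow the
#' Bernacchi et al. (2001) Arrhenius parameterization, the standard choice in
#' P-model implementations. The reference values are partial pressures at
#' standard atmosphere and scale linearly with pressure.
#'
#' @param ... Named overrides for any default constant. Unknown names are an
#'   error, so typos cannot silently fall back to defaults.
#'
#' @return An object of class \code{photo_constants}: a named list with fields
#' \describe{
#'   \item{gamma_star25}{CO2 compensation point without dark respiration at
#'     25 degC and standard pressure, Pa (4.332).}
#'   \item{kc25, ko25}{Michaelis constants of Rubisco for CO2 and O2 at
#'     25 degC, Pa (39.97 and 27480).}
#'   \item{ea_gamma_star, ea_kc, ea_ko}{Arrhenius activation energies,
#'     J mol-1 (37830, 79430, 36380).}
#'   \item{o2_frac}{O2 mole fraction of dry air (0.2095); the O2 partial
#'     pressure is \code{o2_frac * patm}.}
#'   \item{beta}{Unit-cost ratio of maintaining carboxylation versus
#'     transpiration capacity in the least-cost optimal chi (146).}
#'   \item{phi0}{Intrinsic quantum yield of photosynthesis, mol CO2 mol-1
#'     photons (0.035, absorptance included; calibrated so the reference
#'     temperate growth state, 25 degC / 1 kPa / 400 ppm / 800 umol m-2 s-1,
#'     assimilates 13.9 umol CO2 m-2 s-1).}
#'   \item{theta_j}{Curvature of the non-rectangular hyperbolic light response
#'     of electron transport (0.85).}
#'   \item{c_jmax}{Marginal maintenance cost of electron-transport capacity
#'     per unit J_max, in units of assimilation (0.05336251); together with
#'     \code{theta_j} this sets the optimal J_max and the realized co-limited
#'     assimilation.}
#'   \item{lambda_water}{Marginal water cost used by the instantaneous
#'     stomatal optimization, mol CO2 (mol H2O)-1 (4.5105e-4; calibrated so
#'     the minute-scale stomatal closure after a 400-to-800 ppm CO2 step at
#'     fixed biochemistry is 23.5 percent).}
#'   \item{gamma_ratio}{Long-term operational ratio g_s : g_smax (0.25), the
#'     conservative setpoint plants maintain within the functional-control
#'     region of the stomatal aperture curve.}
#'   \item{rd_frac}{Dark respiration as a fraction of V_cmax subtracted from
#'     net assimilation (0 by default: the idealized scenarios track gross
#'     assimilation).}
#' }
#'
#' @examples
#' cs <- photo_constants()
#' cs$beta
#' photo_constants(beta = 200, gamma_ratio = 0.3)$gamma_ratio
#' @export
photo_constants <- function(...) {
  cs <- list(
    gamma_star25  = 4.332,
    kc25          = 39.97,
    ko25          = 27480,
    ea_gamma_star = 37830,
    ea_kc         = 79430,
    ea_ko         = 36380,
    o2_frac       = 0.2095,
    beta          = 146,
    phi0          = 0.035,
    theta_j       = 0.85,
    c_jmax        = 0.05336251,
    lambda_water  = 4.5105e-4,
    gamma_ratio   = 0.25,
    rd_frac       = 0
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all constant overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(cs))
    if (length(unknown))
      stop("unknown constant(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    cs[names(dots)] <- dots
  }
  validate_photo_constants(structure(cs, class = "photo_constants"))
}

validate_photo_constants <- function(cs) {
  num <- vapply(cs, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num))
    stop("constants must be finite numeric scalars: ",
         paste(names(cs)[!num], collapse = ", "), call. = FALSE)
  pos <- c("gamma_star25", "kc25", "ko25", "ea_gamma_star", "ea_kc", "ea_ko",
           "o2_frac", "beta", "phi0", "theta_j", "c_jmax", "lambda_water")
  bad <- pos[vapply(pos, function(f) cs[[f]] <= 0, logical(1))]
  if (length(bad))
    stop("constants must be strictly positive: ", paste(bad, collapse = ", "), call. = FALSE)
  if (cs$gamma_ratio <= 0 || cs$gamma_ratio >= 1)
    stop("gamma_ratio must lie in (0, 1)", call. = FALSE)
  if (cs$phi0 >= 0.125)
    stop("phi0 must be below the theoretical maximum of 0.125 mol CO2 mol-1 photons",
         call. = FALSE)
  if (cs$theta_j >= 1)
    stop("theta_j must lie in (0, 1)", call. = FALSE)
  if (cs$rd_frac < 0 || cs$rd_frac >= 1)
    stop("rd_frac must lie in [0, 1)", call. = FALSE)
  cs
}

#' @export
print.photo_constants <- function(x, ...) {
  cat("<photo_constants>\n")
  for (f in names(x)) cat(sprintf("  %-14s %g\n", f, x[[f]]))
  invisible(x)
}

#' Environmental forcing at one instant
#'
#' The five forcing variables the framework responds to. Vapour pressure
#' deficit is taken in Pa to keep it commensurate with the internal
#' partial-pressure bookkeeping (1 kPa = 1000 Pa).
#'
#' @param temp_c Air (= leaf) temperature, degC. Validated to [-30, 60].
#' @param vpd Vapour pressure deficit of the air, Pa. Must be > 0.
#' @param ca_ppm Ambient CO2 mole fraction, umol mol-1. Must be > 0.
#' @param ppfd Photosynthetic photon flux density, umol m-2 s-1. Must be >= 0.
#' @param patm Atmospheric pressure, Pa (default 101325).
#'
#' @return An object of class \code{environment_state}.
#' @examples
#' environment_state(temp_c = 25, vpd = 1000, ca_ppm = 400, ppfd = 800)
#' @export
environment_state <- function(temp_c = 25, vpd = 1000, ca_ppm = 400,
                              ppfd = 800, patm = 101325) {
  env <- list(temp_c = temp_c, vpd = vpd, ca_ppm = ca_ppm,
              ppfd = ppfd, patm = patm)
  num <- vapply(env, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(num))
    stop("environment fields must be finite numeric scalars: ",
         paste(names(env)[!num], collapse = ", "), call. = FALSE)
  if (temp_c < -30 || temp_c > 60)
    stop("temp_c out of validated range [-30, 60] degC", call. = FALSE)
  if (vpd <= 0) stop("vpd must be > 0 (Pa)", call. = FALSE)
  if (ca_ppm <= 0) stop("ca_ppm must be > 0", call. = FALSE)
  if (ppfd < 0) stop("ppfd must be >= 0", call. = FALSE)
  if (patm <= 0) stop("patm must be > 0 (Pa)", call. = FALSE)
  structure(env, class = "environment_state")
}

#' @export
print.environment_state <- function(x, ...) {
  cat(sprintf(
    "<environment_state> T = %g degC, VPD = %g Pa, ca = %g ppm, PPFD = %g umol m-2 s-1, P = %g Pa\n",
    x$temp_c, x$vpd, x$ca_ppm, x$ppfd, x$patm))
  invisible(x)
}

as_environment_state <- function(x) {
  if (inherits(x, "environment_state")) return(x)
  if (is.list(x)) return(do.call(environment_state, x))
  stop("cannot interpret object as an environment_state", call. = FALSE)
}
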