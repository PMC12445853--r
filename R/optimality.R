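## Eco-evolutionary optimality predictions: optimal chi, coordinated
## (acclimated) biochemistry, and the instantaneous stomatal optimum.

#' Least-cost optimal ci:ca ratio
#'
#' The optimal ratio of leaf-internal to ambient CO2 from least-cost theory:
#' \deqn{\chi = \Gamma^*/c_a + (1 - \Gamma^*/c_a)\,\xi / (\xi + \sqrt{D}),
#'   \qquad \xi = \sqrt{\beta (K + \Gamma^*) / (1.6\,\eta^*)},}
#' with vapour pressure deficit D in Pa, so \eqn{\xi} carries units of
#' \eqn{\sqrt{Pa}}. \eqn{\chi} acts as the setpoint around which the
#' fast stomatal dynamics operate, itself acclimating on the week scale.
#'
#' @param env An [environment_state()].
#' @param constants A [photo_constants()] object.
#' @return A list:
#'   \item{xi}{sensitivity of chi to the square root of VPD, Pa^0.5;}
#'   \item{chi}{optimal ci:ca, in (GammaStar/ca, 1);}
#'   \item{m}{CO2 limitation factor of light-limited assimilation
#'     \eqn{(c_i-\Gamma^*)/(c_i+2\Gamma^*)} at the acclimated ci;}
#'   \item{ci_acclim}{acclimated leaf-internal CO2, Pa;}
#'   \item{gamma_star, big_k}{the underlying Pa-valued constants at this
#'     temperature and pressure.}
#' @examples
#' chi_optimal(environment_state(vpd = 1000))$chi  # about 0.75
#' chi_optimal(environment_state(vpd = 2000))$chi  # about 0.69
#' @export
chi_optimal <- function(env, constants = photo_constants()) {
  env <- as_environment_state(env)
  gstar <- gamma_star(env$temp_c, env$patm, constants)
  bigk  <- michaelis_k(env$temp_c, env$patm, constants)
  eta   <- viscosity_ratio(env$temp_c)
  ca_pa <- ppm_to_pa(env$ca_ppm, env$patm)
  xi    <- sqrt(constants$beta * (bigk + gstar) / (1.6 * eta))
  g_ca  <- gstar / ca_pa
  chi   <- g_ca + (1 - g_ca) * xi / (xi + sqrt(env$vpd))
  ci    <- chi * ca_pa
  list(xi = xi, chi = chi,
       m = (ci - gstar) / (ci + 2 * gstar),
       ci_acclim = ci, gamma_star = gstar, big_k = bigk)
}

## Optimal electron-transport capacity factors: omega scales the optimal
## J_max (J_max = 4 phi0 I omega) and omega* the realized co-limited rate
## (J = 4 phi0 I omega* / (2 theta)), given the marginal cost c of
## maintaining J_max and the light-response curvature theta.
jmax_omega <- function(m, theta, c_cost) {
  cm <- 4 * c_cost / m
  if (cm * (1 - theta * cm) <= 0) return(NA_real_)
  v <- 1 / (cm * (1 - theta * cm)) - 4 * theta
  if (v < 0) return(NA_real_)
  cap_p  <- (((1 / 1.4) - 0.7)^2 / (1 - theta)) + 3.4
  roots  <- sort(Re(polyroot(c(-(cap_p * theta), cap_p, -1))))
  m_star <- 4 * c_cost / roots[1]
  if (m < m_star) -(1 - 2 * theta) - sqrt((1 - theta) * v)
  else            -(1 - 2 * theta) + sqrt((1 - theta) * v)
}

jmax_omega_star <- function(omega, theta) {
  1 + omega - sqrt((1 + omega)^2 - 4 * theta * omega)
}

#' Fully acclimated leaf state under the coordination hypothesis
#'
#' Computes the trait combination an unstressed leaf converges to under
#' steady growth conditions: optimal \eqn{\chi} (least-cost), optimal
#' \eqn{J_{max}} (marginal electron-transport cost \code{c_jmax} against the
#' curvature \code{theta_j}), the light-use-efficiency assimilation rate at
#' the co-limited point, \eqn{V_{cmax}} coordinated so that the Rubisco- and
#' RuBP-limited rates meet exactly at the acclimated \eqn{c_i}, and the
#' stomatal conductance that sustains this \eqn{c_i} by diffusion.
#'
#' @inheritParams chi_optimal
#' @return A list with \code{chi}, \code{ci} (Pa), \code{m}, \code{mc},
#'   \code{omega}, \code{omega_star}, \code{a_leaf} (umol m-2 s-1),
#'   \code{vcmax}, \code{jmax} (umol m-2 s-1), \code{gs} (mol H2O m-2 s-1)
#'   and \code{gsmax} (\code{gs / gamma_ratio}).
#' @examples
#' st <- acclimated_state(environment_state())
#' round(st$a_leaf, 1)  # 13.9 under the reference temperate conditions
#' @export
acclimated_state <- function(env, constants = photo_constants()) {
  env <- as_environment_state(env)
  if (env$ppfd <= 0)
    stop("acclimation requires ppfd > 0", call. = FALSE)
  co <- chi_optimal(env, constants)
  th <- constants$theta_j
  om <- jmax_omega(co$m, th, constants$c_jmax)
  if (is.na(om)) {
    warning("light environment cannot pay the J_max maintenance cost; assimilation set to 0")
    return(list(chi = co$chi, ci = co$ci_acclim, m = co$m, mc = NA_real_,
                omega = NA_real_, omega_star = NA_real_, a_leaf = 0,
                vcmax = 0, jmax = 0, gs = NA_real_, gsmax = NA_real_))
  }
  oms <- jmax_omega_star(om, th)
  ci  <- co$ci_acclim
  mc  <- (ci - co$gamma_star) / (ci + co$big_k)
  a   <- constants$phi0 * env$ppfd * co$m * oms / (2 * th)
  vcmax <- a / mc
  jmax  <- 4 * constants$phi0 * env$ppfd * om
  dc_ppm <- env$ca_ppm * (1 - co$chi)
  gs <- 1.6 * a / dc_ppm                    # mol H2O m-2 s-1
  list(chi = co$chi, ci = ci, m = co$m, mc = mc, omega = om,
       omega_star = oms, a_leaf = a, vcmax = vcmax, jmax = jmax,
       gs = gs, gsmax = gs / constants$gamma_ratio)
}

#' Acclimated maximum carboxylation rate
#'
#' \eqn{V_{cmax}} coordinated to the growth environment: the value at which
#' the Rubisco-limited rate equals the RuBP-limited rate at the acclimated
#' \eqn{c_i = \chi c_a} under growth light. See [acclimated_state()].
#'
#' @inheritParams chi_optimal
#' @return V_cmax, umol m-2 s-1.
#' @export
acclimated_vcmax <- function(env, constants = photo_constants()) {
  acclimated_state(env, constants)$vcmax
}

#' Light-use-efficiency assimilation at the acclimated state
#'
#' \eqn{A_{leaf} = \phi_0 I m \,\omega^* / (2\theta)}: the co-limited
#' assimilation rate of a leaf whose biochemistry and stomata are fully
#' acclimated to the environment. Returns 0 (with a warning) when the light
#' environment cannot pay the electron-transport maintenance cost.
#'
#' @inheritParams chi_optimal
#' @return A_leaf, umol CO2 m-2 s-1.
#' @examples
#' lue_assimilation(environment_state(ppfd = 0))  # 0 in darkness
#' @export
lue_assimilation <- function(env, constants = photo_constants()) {
  env <- as_environment_state(env)
  if (env$ppfd == 0) return(0)
  acclimated_state(env, constants)$a_leaf
}

#' Acclimated stomatal conductance
#'
#' The conductance (to water vapour) that sustains the acclimated
#' \eqn{c_i = \chi c_a} by diffusion:
#' \eqn{g_s = 1.6 A_{leaf} / (c_a (1 - \chi))} with \eqn{c_a} as a mole
#' fraction. Feeding it back through [solve_ci()] reproduces the acclimated
#' \eqn{c_i}.
#'
#' @inheritParams chi_optimal
#' @return g_s, mol H2O m-2 s-1.
#' @export
acclimated_gs <- function(env, constants = photo_constants()) {
  acclimated_state(env, constants)$gs
}

#' Instantaneous stomatal optimum at fixed biochemistry
#'
#' The minute-scale stomatal response: with \eqn{V_{cmax}} and \eqn{J_{max}}
#' frozen at their current values, the leaf opens or closes stomata to
#' maximize carbon gain net of a water cost proportional to transpiration,
#' \deqn{F(g_s) = A(g_s) - \lambda\, g_s D / P_{atm},}
#' where \eqn{A(g_s)} couples the demand curve to the supply line (see
#' [solve_ci()]) and \eqn{\lambda} (\code{constants$lambda_water}) is the
#' constant marginal water-use efficiency, mol CO2 (mol H2O)-1. The
#' objective is concave; the maximum is located by deterministic
#' golden-section search.
#'
#' @inheritParams chi_optimal
#' @param vcmax,jmax Fixed (pre-acclimation) biochemical capacities,
#'   umol m-2 s-1.
#' @param lambda Marginal water cost override; default
#'   \code{constants$lambda_water}.
#' @param gs_upper Upper bound of the search interval, mol H2O m-2 s-1.
#' @param demand Demand branch passed to [solve_ci()].
#' @return A list with \code{gs} (mol H2O m-2 s-1), \code{ci} (Pa),
#'   \code{a_leaf} (umol m-2 s-1) and \code{objective} at the optimum.
#'   A warning is raised if the optimum sits at the search boundary.
#' @examples
#' env <- environment_state(ca_ppm = 800)
#' st  <- acclimated_state(environment_state())
#' instantaneous_gs(env, st$vcmax, st$jmax)$gs  # closure under elevated CO2
#' @export
instantaneous_gs <- function(env, vcmax, jmax, constants = photo_constants(),
                             lambda = NULL, gs_upper = 10,
                             demand = c("rubp", "min", "rubisco")) {
  demand <- match.arg(demand)
  env <- as_environment_state(env)
  if (vcmax <= 0) stop("vcmax must be > 0", call. = FALSE)
  if (is.null(lambda)) lambda <- constants$lambda_water
  dhat <- env$vpd / env$patm              # mole-fraction deficit
  j <- electron_transport(env$ppfd, jmax, constants)
  objective <- function(gs) {
    ci <- solve_ci(gs, env, vcmax, jmax, constants, demand = demand)
    a  <- demand_fun(demand, vcmax, j, env$temp_c, env$patm, constants)(ci)
    a - lambda * gs * dhat * 1e6          # both terms in umol m-2 s-1
  }
  opt <- stats::optimize(objective, c(1e-8, gs_upper), maximum = TRUE,
                         tol = 1e-10)
  if (opt$maximum < 1e-6 || opt$maximum > gs_upper - 1e-6)
    warning("instantaneous gs optimum at the search boundary; objective may be monotone")
  ci <- solve_ci(opt$maximum, env, vcmax, jmax, constants, demand = demand)
  a  <- demand_fun(demand, vcmax, j, env$temp_c, env$patm, constants)(ci)
  list(gs = opt$maximum, ci = ci, a_leaf = a, objective = opt$objective)
}
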