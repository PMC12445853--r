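## FvCB demand curve, stomatal supply function, and the coupled ci solver.

#' Rubisco-limited assimilation rate
#'
#' \eqn{A_c = V_{cmax} (c_i - \Gamma^*) / (c_i + K)}. Below the compensation
#' point the rate is negative (net efflux), never an error.
#'
#' @param ci_pa Leaf-internal CO2 partial pressure, Pa (>= 0).
#' @param vcmax Maximum carboxylation rate, umol m-2 s-1 (>= 0).
#' @param temp_c Leaf temperature, degC.
#' @param patm Atmospheric pressure, Pa.
#' @param constants A [photo_constants()] object.
#' @return Assimilation rate, umol CO2 m-2 s-1.
#' @examples
#' assimilation_rubisco(gamma_star(25), vcmax = 50)  # 0 at the compensation point
#' @export
assimilation_rubisco <- function(ci_pa, vcmax, temp_c = 25, patm = .P_STD,
                                 constants = photo_constants()) {
  if (any(ci_pa < 0) || any(vcmax < 0))
    stop("ci_pa and vcmax must be >= 0", call. = FALSE)
  gs <- gamma_star(temp_c, patm, constants)
  k  <- michaelis_k(temp_c, patm, constants)
  vcmax * (ci_pa - gs) / (ci_pa + k)
}

#' RuBP-regeneration-limited assimilation rate
#'
#' \eqn{A_j = (J/4) (c_i - \Gamma^*) / (c_i + 2\Gamma^*)} for a realized
#' electron transport rate J (see [electron_transport()]).
#'
#' @inheritParams assimilation_rubisco
#' @param j Realized electron transport rate, umol m-2 s-1 (>= 0).
#' @return Assimilation rate, umol CO2 m-2 s-1; approaches J/4 at saturating
#'   CO2.
#' @export
assimilation_rubp <- function(ci_pa, j, temp_c = 25, patm = .P_STD,
                              constants = photo_constants()) {
  if (any(ci_pa < 0) || any(j < 0))
    stop("ci_pa and j must be >= 0", call. = FALSE)
  gs <- gamma_star(temp_c, patm, constants)
  (j / 4) * (ci_pa - gs) / (ci_pa + 2 * gs)
}

#' Realized electron transport rate
#'
#' Saturating light response of electron transport as the smaller root of the
#' non-rectangular hyperbola
#' \eqn{\theta J^2 - (4\phi_0 I + J_{max}) J + 4\phi_0 I J_{max} = 0},
#' where \eqn{4\phi_0 I} is the light-limited rate implied by the intrinsic
#' quantum yield. \code{jmax = Inf} returns the light-limited limit.
#'
#' @param ppfd Photosynthetic photon flux density, umol m-2 s-1 (>= 0).
#' @param jmax Maximum electron transport rate, umol m-2 s-1 (> 0, may be Inf).
#' @param constants A [photo_constants()] object (uses \code{phi0},
#'   \code{theta_j}).
#' @return J, umol m-2 s-1, with \eqn{0 \le J \le \min(4\phi_0 I, J_{max})}.
#' @examples
#' electron_transport(0, 120)            # 0 in darkness
#' electron_transport(800, Inf, photo_constants())  # light-limited: 4 phi0 I
#' @export
electron_transport <- function(ppfd, jmax, constants = photo_constants()) {
  if (any(ppfd < 0)) stop("ppfd must be >= 0", call. = FALSE)
  if (any(jmax <= 0)) stop("jmax must be > 0", call. = FALSE)
  il <- 4 * constants$phi0 * ppfd          # light-limited rate
  th <- constants$theta_j
  nrh <- function(il, jx)
    ((il + jx) - sqrt((il + jx)^2 - 4 * th * il * jx)) / (2 * th)
  ifelse(il == 0, 0, ifelse(is.infinite(jmax), il, nrh(il, jmax)))
}

#' Net assimilation as the minimum of the two FvCB limitations
#'
#' Evaluates both limitation branches at the given \eqn{c_i} and returns the
#' operative minimum with a limitation flag; exact ties are labelled
#' \code{"rubisco"} for deterministic output. If \code{rd_frac > 0} in the
#' constants, dark respiration \code{rd_frac * vcmax} is subtracted from
#' \code{a_net} (the limitation flag is decided on gross rates).
#'
#' @inheritParams assimilation_rubisco
#' @param j Realized electron transport rate, umol m-2 s-1.
#' @return A list with \code{a_net}, \code{limitation} ("rubisco" or "rubp"),
#'   \code{a_c} and \code{a_j}.
#' @export
net_assimilation <- function(ci_pa, vcmax, j, temp_c = 25, patm = .P_STD,
                             constants = photo_constants()) {
  a_c <- assimilation_rubisco(ci_pa, vcmax, temp_c, patm, constants)
  a_j <- assimilation_rubp(ci_pa, j, temp_c, patm, constants)
  lim <- if (a_c <= a_j) "rubisco" else "rubp"
  list(a_net = min(a_c, a_j) - constants$rd_frac * vcmax,
       limitation = lim, a_c = a_c, a_j = a_j)
}

demand_fun <- function(branch, vcmax, j, temp_c, patm, constants) {
  switch(branch,
    rubp    = function(ci) assimilation_rubp(ci, j, temp_c, patm, constants),
    rubisco = function(ci) assimilation_rubisco(ci, vcmax, temp_c, patm, constants),
    min     = function(ci) min(
                assimilation_rubisco(ci, vcmax, temp_c, patm, constants),
                assimilation_rubp(ci, j, temp_c, patm, constants)),
    stop("unknown demand branch: ", branch, call. = FALSE))
}

#' Solve leaf-internal CO2 from supply-demand balance
#'
#' Finds the \eqn{c_i} at which the FvCB demand curve intersects the stomatal
#' supply line \eqn{A = (g_s / 1.6) (c_a - c_i) / P_{atm}} (conductance given
#' for water vapour; division by 1.6 converts to the CO2 diffusivity). The
#' demand is strictly increasing and the supply strictly decreasing in
#' \eqn{c_i}, so the root on \eqn{[\Gamma^*, c_a]} is unique; it is located
#' by bracketed root finding to near machine precision.
#'
#' @param gs Stomatal conductance, mol m-2 s-1. Interpreted per
#'   \code{gs_units}.
#' @param env An [environment_state()].
#' @param vcmax Maximum carboxylation rate, umol m-2 s-1.
#' @param jmax Maximum electron transport rate, umol m-2 s-1.
#' @param constants A [photo_constants()] object.
#' @param demand Which demand branch intersects the supply line:
#'   \code{"rubp"} (RuBP-regeneration-limited, the branch operative around
#'   the coordinated state and the engine default), \code{"min"} (full FvCB
#'   minimum) or \code{"rubisco"}.
#' @param gs_units \code{"h2o"} (default; conductance to water vapour, as
#'   reported throughout) or \code{"co2"}.
#' @return \eqn{c_i} in Pa, with \eqn{\Gamma^* \le c_i \le c_a}.
#' @examples
#' env <- environment_state()
#' solve_ci(gs = 1e4, env, vcmax = 50, jmax = 120)  # huge gs: ci -> ca
#' @export
solve_ci <- function(gs, env, vcmax, jmax, constants = photo_constants(),
                     demand = c("rubp", "min", "rubisco"),
                     gs_units = c("h2o", "co2")) {
  demand <- match.arg(demand)
  gs_units <- match.arg(gs_units)
  env <- as_environment_state(env)
  if (gs <= 0) stop("gs must be > 0", call. = FALSE)
  gc <- if (gs_units == "h2o") gs / 1.6 else gs
  gstar <- gamma_star(env$temp_c, env$patm, constants)
  ca_pa <- ppm_to_pa(env$ca_ppm, env$patm)
  if (ca_pa <= gstar)
    stop("ambient CO2 at or below the compensation point: no positive-assimilation root",
         call. = FALSE)
  j <- electron_transport(env$ppfd, jmax, constants)
  dem <- demand_fun(demand, vcmax, j, env$temp_c, env$patm, constants)
  supply <- function(ci) gc * (ca_pa - ci) / env$patm * 1e6   # umol m-2 s-1
  f <- function(ci) dem(ci) - supply(ci)
  lo <- gstar + 1e-6
  if (f(lo) > 0 || f(ca_pa) < 0)
    stop(sprintf(
      "no supply-demand root in [GammaStar, ca]: f(lo) = %.3g, f(ca) = %.3g (gs = %g, ca = %g ppm)",
      f(lo), f(ca_pa), gs, env$ca_ppm), call. = FALSE)
  root <- stats::uniroot(f, c(lo, ca_pa), tol = .Machine$double.eps^0.75,
                         maxiter = 200L)
  ci <- root$root
  if (abs(f(ci)) > 1e-8)
    warning("supply-demand residual above 1e-8 umol m-2 s-1 at the returned ci")
  ci
}
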