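## Brute-force oracles kept independent of the package's solver internals.

## Supply-demand intersection by dense grid bracketing on [GammaStar, ca].
grid_solve_ci <- function(gs_h2o, env, vcmax, jmax, constants,
                          branch = "rubp", n_grid = 400000L) {
  gc <- gs_h2o / 1.6
  gstar <- gamma_star(env$temp_c, env$patm, constants)
  ca_pa <- ppm_to_pa(env$ca_ppm, env$patm)
  j <- electron_transport(env$ppfd, jmax, constants)
  ci <- seq(gstar + 1e-9, ca_pa, length.out = n_grid)
  dem <- if (branch == "rubp") {
    assimilation_rubp(ci, j, env$temp_c, env$patm, constants)
  } else {
    pmin(assimilation_rubp(ci, j, env$temp_c, env$patm, constants),
         assimilation_rubisco(ci, vcmax, env$temp_c, env$patm, constants))
  }
  sup <- gc * (ca_pa - ci) / env$patm * 1e6
  ci[which.min(abs(dem - sup))]
}

## Closed-form ci for the RuBP-limited branch: the supply line
## gc (ca - ci) / P = (J/4)(ci - G)/(ci + 2G) reduces to a quadratic in ci.
quadratic_ci_rubp <- function(gs_h2o, env, jmax, constants) {
  gc <- gs_h2o / 1.6
  gstar <- gamma_star(env$temp_c, env$patm, constants)
  ca_pa <- ppm_to_pa(env$ca_ppm, env$patm)
  j <- electron_transport(env$ppfd, jmax, constants)
  k1 <- j / 4
  s  <- gc / env$patm * 1e6           # umol m-2 s-1 per Pa of gradient
  ## s (ca - ci)(ci + 2G) = k1 (ci - G)  ->  a ci^2 + b ci + c = 0
  a <- -s
  b <- s * (ca_pa - 2 * gstar) - k1
  c <- 2 * s * gstar * ca_pa + k1 * gstar
  roots <- sort(Re(polyroot(c(c, b, a))))
  roots[roots >= gstar & roots <= ca_pa][1]
}

## Instantaneous stomatal optimum by grid search over gs.
grid_instantaneous_gs <- function(env, vcmax, jmax, constants,
                                  lambda = constants$lambda_water,
                                  gs_grid = seq(1e-3, 1.5, length.out = 100000L)) {
  j <- electron_transport(env$ppfd, jmax, constants)
  dhat <- env$vpd / env$patm
  obj <- vapply(gs_grid, function(gs) {
    ci <- solve_ci(gs, env, vcmax, jmax, constants, demand = "rubp")
    assimilation_rubp(ci, j, env$temp_c, env$patm, constants) -
      lambda * gs * dhat * 1e6
  }, numeric(1))
  gs_grid[which.max(obj)]
}

ref_env <- function(...) {
  args <- list(temp_c = 25, vpd = 1000, ca_ppm = 400, ppfd = 800,
               patm = 101325)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(environment_state, args)
}
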