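## Replaying an environmental step change through the five timescale states.

STEP_LABELS <- c("initial_optimum", "instantaneous", "stomatal_physiology",
                 "biochemical_acclimation", "anatomical_development")
STEP_TIMESCALES <- c("initial", "seconds", "minutes", "weeks",
                     "seasonal and longer")
LAPSE_TRAITS <- c("a_leaf", "chi_opt", "ci", "gs", "vcmax", "jmax", "gsmax")

new_leaf_state <- function(ci, gs, vcmax, jmax, gsmax, chi_opt, a_leaf, env) {
  ca_pa <- ppm_to_pa(env$ca_ppm, env$patm)
  list(ci = ci, gs = gs, vcmax = vcmax, jmax = jmax, gsmax = gsmax,
       chi_opt = chi_opt, a_leaf = a_leaf,
       ratio_ci = (ci / ca_pa) / chi_opt,   # recomputed, never stored stale
       ratio_gs = gs / gsmax)
}

#' Initial optimized leaf state
#'
#' Step 0 of a scenario: the trait combination fully acclimated to the given
#' environment, with the anatomical maximum conductance positioned so that
#' the operational conductance sits at the conservative ratio
#' \eqn{\gamma = g_s : g_{smax}}. By construction \code{ratio_ci = 1} and
#' \code{ratio_gs = gamma_ratio}.
#'
#' @param env An [environment_state()].
#' @param constants A [photo_constants()] object.
#' @return A leaf-state list: \code{ci} (Pa), \code{gs}, \code{gsmax}
#'   (mol H2O m-2 s-1), \code{vcmax}, \code{jmax}, \code{a_leaf}
#'   (umol m-2 s-1), \code{chi_opt}, \code{ratio_ci}, \code{ratio_gs}.
#' @examples
#' st <- initial_state(environment_state())
#' st$ratio_ci   # 1
#' st$ratio_gs   # 0.25
#' @export
initial_state <- function(env, constants = photo_constants()) {
  env <- as_environment_state(env)
  acc <- acclimated_state(env, constants)
  new_leaf_state(ci = acc$ci, gs = acc$gs, vcmax = acc$vcmax,
                 jmax = acc$jmax, gsmax = acc$gsmax, chi_opt = acc$chi,
                 a_leaf = acc$a_leaf, env = env)
}

#' Anatomical maximum conductance from the operational conductance
#'
#' Inverts the conservative operational ratio: \eqn{g_{smax} =
#' g_{s(op)} / \gamma}, so that \code{gs_operational / gsmax == gamma_ratio}
#' exactly.
#'
#' @param gs_operational Operational stomatal conductance, mol m-2 s-1 (> 0).
#' @param gamma_ratio Long-term ratio g_s:g_smax in (0, 1); default 0.25.
#' @return g_smax in the same units as the input.
#' @examples
#' gsmax_from_operational(0.22, 0.25)  # 0.88
#' @export
gsmax_from_operational <- function(gs_operational, gamma_ratio = 0.25) {
  if (any(gs_operational <= 0)) stop("gs_operational must be > 0", call. = FALSE)
  if (any(gamma_ratio <= 0 | gamma_ratio >= 1))
    stop("gamma_ratio must lie in (0, 1)", call. = FALSE)
  gs_operational / gamma_ratio
}

#' Replay an environmental step change across the five timescale states
#'
#' Applies a perturbation in ambient CO2 and/or VPD and steps the leaf
#' through the temporally separated responses:
#' \enumerate{
#'   \item \strong{initial_optimum}: fully acclimated state under \code{env0}.
#'   \item \strong{instantaneous} (seconds): the new environment with every
#'     trait frozen; only \eqn{c_i} (and hence \eqn{A_{leaf}}) re-equilibrates
#'     through the supply-demand balance.
#'   \item \strong{stomatal_physiology} (minutes): stomatal aperture moves to
#'     the instantaneous optimum at fixed biochemistry
#'     ([instantaneous_gs()]), clipped at the anatomical ceiling
#'     \eqn{g_{smax}} if necessary.
#'   \item \strong{biochemical_acclimation} (weeks): \eqn{V_{cmax}}
#'     re-coordinates to the new environment and \eqn{g_s} is re-optimized
#'     against the new biochemistry so that \eqn{c_i = \chi c_a}. By default
#'     \eqn{J_{max}} keeps its initial value (\code{jmax_acclimate = FALSE}),
#'     which reproduces the small assimilation declines that accompany the
#'     stomatal and biochemical adjustments; with
#'     \code{jmax_acclimate = TRUE} electron-transport capacity
#'     re-optimizes too and step 4 equals the fresh optimum in every field.
#'   \item \strong{anatomical_development} (seasonal and longer): new leaves
#'     shift \eqn{g_{smax}} so the operational ratio returns to
#'     \eqn{\gamma}.
#' }
#'
#' @param env0,env1 [environment_state()] objects. They may differ only in
#'   \code{ca_ppm} and/or \code{vpd}; differing temperature, light or
#'   pressure is rejected.
#' @param constants A [photo_constants()] object.
#' @param jmax_acclimate Logical; re-optimize J_max at the week-scale step
#'   (default \code{FALSE}, see above).
#' @param clip_gs Logical; clip the minute-scale stomatal optimum at
#'   \eqn{g_{smax}} (default \code{TRUE}). When clipping occurs the returned
#'   object carries \code{functional_control_exceeded = TRUE}.
#' @param scenario Name stored in the output metadata.
#' @return An object of class \code{leaf_timelapse}: list with
#'   \code{steps} (5 leaf states), \code{env} (per-step environments),
#'   \code{table} (long data frame: scenario, step_index, step_label,
#'   timescale, trait, value), \code{metadata} (constants, flags), and
#'   \code{functional_control_exceeded}.
#' @examples
#' tl <- run_scenario(environment_state(ca_ppm = 400),
#'                    environment_state(ca_ppm = 800))
#' tl$steps[[2]]$ratio_ci   # about 1.15: ci overshoots the new setpoint
#' @export
run_scenario <- function(env0, env1, constants = photo_constants(),
                         jmax_acclimate = FALSE, clip_gs = TRUE,
                         scenario = "custom") {
  env0 <- as_environment_state(env0)
  env1 <- as_environment_state(env1)
  fixed <- c("temp_c", "ppfd", "patm")
  differs <- fixed[vapply(fixed, function(f) env0[[f]] != env1[[f]], logical(1))]
  if (length(differs))
    stop("only ca_ppm and vpd perturbations are supported; these differ: ",
         paste(differs, collapse = ", "), call. = FALSE)

  fail <- function(stage, e)
    stop(sprintf("scenario stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)

  ## step 0: initial optimum under env0
  s0 <- tryCatch(initial_state(env0, constants),
                 error = function(e) fail("initial_optimum", e))
  chi1 <- chi_optimal(env1, constants)$chi
  j0 <- electron_transport(env1$ppfd, s0$jmax, constants)
  aj <- function(ci) assimilation_rubp(ci, j0, env1$temp_c, env1$patm, constants)

  ## step 1: seconds -- all traits frozen, ci re-equilibrates
  s1 <- tryCatch({
    ci1 <- solve_ci(s0$gs, env1, s0$vcmax, s0$jmax, constants, demand = "rubp")
    new_leaf_state(ci1, s0$gs, s0$vcmax, s0$jmax, s0$gsmax, chi1, aj(ci1), env1)
  }, error = function(e) fail("instantaneous", e))

  ## step 2: minutes -- stomatal aperture re-optimized at fixed biochemistry
  exceeded <- FALSE
  s2 <- tryCatch({
    opt <- instantaneous_gs(env1, s0$vcmax, s0$jmax, constants)
    gs2 <- opt$gs
    if (clip_gs && gs2 > s0$gsmax) {
      gs2 <- s0$gsmax
      exceeded <- TRUE
    }
    ci2 <- solve_ci(gs2, env1, s0$vcmax, s0$jmax, constants, demand = "rubp")
    new_leaf_state(ci2, gs2, s0$vcmax, s0$jmax, s0$gsmax, chi1, aj(ci2), env1)
  }, error = function(e) fail("stomatal_physiology", e))

  ## step 3: weeks -- biochemistry re-coordinates, gs follows the new setpoint
  s3 <- tryCatch({
    acc <- acclimated_state(env1, constants)
    jmax3 <- if (jmax_acclimate) acc$jmax else s0$jmax
    j3 <- electron_transport(env1$ppfd, jmax3, constants)
    ci3 <- acc$ci
    a3 <- assimilation_rubp(ci3, j3, env1$temp_c, env1$patm, constants)
    gs3 <- 1.6 * a3 / (env1$ca_ppm * (1 - acc$chi))
    new_leaf_state(ci3, gs3, acc$vcmax, jmax3, s0$gsmax, chi1, a3, env1)
  }, error = function(e) fail("biochemical_acclimation", e))

  ## step 4: seasonal and longer -- gsmax develops so ratio_gs returns to gamma
  s4 <- new_leaf_state(s3$ci, s3$gs, s3$vcmax, s3$jmax,
                       gsmax_from_operational(s3$gs, constants$gamma_ratio),
                       chi1, s3$a_leaf, env1)

  steps <- list(s0, s1, s2, s3, s4)
  envs  <- list(env0, env1, env1, env1, env1)
  tab <- do.call(rbind, lapply(seq_along(steps), function(i) {
    st <- steps[[i]]
    data.frame(scenario = scenario, step_index = i - 1L,
               step_label = STEP_LABELS[i], timescale = STEP_TIMESCALES[i],
               trait = c(LAPSE_TRAITS, "ratio_ci", "ratio_gs"),
               value = c(st$a_leaf, st$chi_opt, st$ci, st$gs, st$vcmax,
                         st$jmax, st$gsmax, st$ratio_ci, st$ratio_gs),
               stringsAsFactors = FALSE)
  }))
  structure(list(steps = steps, env = envs, table = tab,
                 functional_control_exceeded = exceeded,
                 metadata = list(scenario = scenario,
                                 constants = unclass(constants),
                                 jmax_acclimate = jmax_acclimate,
                                 clip_gs = clip_gs)),
            class = "leaf_timelapse")
}

#' @export
print.leaf_timelapse <- function(x, digits = 4, ...) {
  cat(sprintf("<leaf_timelapse> scenario '%s'\n", x$metadata$scenario))
  wide <- as.data.frame(x)
  print(format(wide, digits = digits), row.names = FALSE)
  if (isTRUE(x$functional_control_exceeded))
    cat("note: instantaneous gs optimum exceeded gsmax (clipped)\n")
  invisible(x)
}

#' @export
as.data.frame.leaf_timelapse <- function(x, ...) {
  tab <- x$table
  traits <- unique(tab$trait)
  wide <- data.frame(step_index = 0:4, step_label = STEP_LABELS,
                     timescale = STEP_TIMESCALES, stringsAsFactors = FALSE)
  for (tr in traits)
    wide[[tr]] <- tab$value[tab$trait == tr][order(tab$step_index[tab$trait == tr])]
  wide
}

#' Normalize a time-lapse to per-trait [0, 1] series
#'
#' Divides each trait's 5-step series by its own maximum within the scenario,
#' so every normalized series lies in [0, 1] with its maximum exactly 1.
#'
#' @param timelapse A \code{leaf_timelapse} from [run_scenario()].
#' @return The same object with a \code{normalized_value} column added to
#'   \code{$table}.
#' @export
normalize_timelapse <- function(timelapse) {
  stopifnot(inherits(timelapse, "leaf_timelapse"))
  tab <- timelapse$table
  if (any(!is.finite(tab$value)))
    stop("non-finite trait values cannot be normalized", call. = FALSE)
  norm <- stats::ave(tab$value, tab$trait, FUN = function(v) {
    mx <- max(v)
    if (mx <= 0) stop("trait series with non-positive maximum cannot be normalized",
                      call. = FALSE)
    v / mx
  })
  timelapse$table$normalized_value <- norm
  timelapse
}

#' Per-step relative changes of every trait
#'
#' Percentage change of each trait between consecutive steps, computed on
#' full-precision values (rounding is left to display), matching the
#' convention in which levels may be reported rounded while the percentage
#' reflects the unrounded series.
#'
#' @param timelapse A \code{leaf_timelapse} from [run_scenario()].
#' @return A data frame with scenario, trait, from_step, to_step,
#'   from_label, to_label, and pct_change = 100 (v1 - v0) / v0.
#' @export
percent_changes <- function(timelapse) {
  stopifnot(inherits(timelapse, "leaf_timelapse"))
  tab <- timelapse$table
  out <- lapply(unique(tab$trait), function(tr) {
    v <- tab$value[tab$trait == tr][order(tab$step_index[tab$trait == tr])]
    data.frame(scenario = timelapse$metadata$scenario, trait = tr,
               from_step = 0:3, to_step = 1:4,
               from_label = STEP_LABELS[1:4], to_label = STEP_LABELS[2:5],
               pct_change = 100 * (v[-1] - v[-5]) / v[-5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
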