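test_that("the initial state sits exactly on both optimality axes", {
  st <- initial_state(ref_env())
  expect_equal(st$ratio_ci, 1)
  expect_equal(st$ratio_gs, 0.25)
  expect_equal(round(st$chi_opt, 2), 0.75)
  expect_equal(round(st$a_leaf, 1), 13.9)
  expect_equal(st$gsmax, st$gs / 0.25)
})

test_that("gsmax inversion of the operational ratio is exact", {
  expect_equal(gsmax_from_operational(0.25, 0.25), 1)
  expect_equal(gsmax_from_operational(0.22, 0.25), 0.88)
  for (gs in c(0.05, 0.22, 0.9))
    expect_equal(gsmax_from_operational(gs, 0.3) * 0.3, gs)
  expect_error(gsmax_from_operational(-0.1, 0.25), "> 0")
  expect_error(gsmax_from_operational(0.2, 1.2), "0, 1")
})

test_that("CO2 doubling reproduces the reported step structure", {
  tl <- run_scenario(ref_env(), ref_env(ca_ppm = 800), scenario = "co2")
  pc <- percent_changes(tl)
  get <- function(tr, to) pc$pct_change[pc$trait == tr & pc$to_step == to]
  ## instantaneous ci release verified against the grid oracle
  cs <- photo_constants()
  s0 <- tl$steps[[1]]
  ci1_oracle <- grid_solve_ci(s0$gs, ref_env(ca_ppm = 800), s0$vcmax,
                              s0$jmax, cs)
  expect_equal(tl$steps[[2]]$ci, ci1_oracle, tolerance = 0.01)
  expect_equal(get("ci", 1), 124, tolerance = 0.01)        # about +124 percent
  expect_equal(get("gs", 2), -23.5, tolerance = 0.001)     # minute-scale closure
  expect_equal(get("vcmax", 3), -23.4, tolerance = 0.015)  # week-scale downshift
  ## ratio_ci overshoots then relaxes monotonically back to 1
  ratios <- vapply(tl$steps, `[[`, numeric(1), "ratio_ci")
  expect_gt(ratios[2], 1)
  expect_true(all(diff(ratios[2:4]) < 0))
  expect_equal(ratios[4], 1, tolerance = 1e-9)
  ## chi steps down once at the perturbation
  expect_equal(get("chi_opt", 1), -1.96, tolerance = 0.01)
  expect_equal(get("chi_opt", 2), 0)
})

test_that("VPD doubling leaves assimilation untouched at the instantaneous step", {
  tl <- run_scenario(ref_env(), ref_env(vpd = 2000), scenario = "vpd")
  a <- vapply(tl$steps, `[[`, numeric(1), "a_leaf")
  ## VPD enters neither the demand curve nor the supply line: structural
  expect_equal(a[2], a[1], tolerance = 1e-12)
  expect_equal(round(a[1], 1), 13.9)
  ## ratio_ci rises only because the setpoint chi fell
  expect_equal(100 * (tl$steps[[2]]$ratio_ci - 1), 9.66, tolerance = 0.01)
  expect_equal(tl$steps[[2]]$ci, tl$steps[[1]]$ci, tolerance = 1e-12)
  ## week-scale coordination lands on the reported conductance
  expect_equal(round(tl$steps[[4]]$gs, 2), 0.17)
})

test_that("gs never exceeds gsmax and the operational ratio returns to gamma", {
  for (env1 in list(ref_env(ca_ppm = 800), ref_env(vpd = 2000),
                    ref_env(ca_ppm = 300, vpd = 1500))) {
    tl <- run_scenario(ref_env(), env1)
    for (st in tl$steps) expect_lte(st$gs, st$gsmax + 1e-12)
    expect_equal(tl$steps[[5]]$ratio_gs, 0.25, tolerance = 1e-12)
  }
})

test_that("an instantaneous optimum above the anatomical ceiling is clipped and flagged", {
  cs <- photo_constants(gamma_ratio = 0.9)   # ceiling barely above operation
  tl <- run_scenario(ref_env(), ref_env(vpd = 500), cs)
  expect_true(tl$functional_control_exceeded)
  expect_equal(tl$steps[[3]]$gs, tl$steps[[1]]$gsmax)
  expect_lte(tl$steps[[3]]$ratio_gs, 1)
  ## without clipping the excursion is allowed through
  tl2 <- run_scenario(ref_env(), ref_env(vpd = 500), cs, clip_gs = FALSE)
  expect_gt(tl2$steps[[3]]$gs, tl2$steps[[1]]$gsmax)
})

test_that("a null perturbation leaves every state except the minute-scale excursion fixed", {
  tl <- run_scenario(ref_env(), ref_env(), scenario = "null")
  s0 <- tl$steps[[1]]
  for (i in c(2, 4, 5)) {
    si <- tl$steps[[i]]
    for (f in c("ci", "gs", "vcmax", "jmax", "gsmax", "chi_opt", "a_leaf"))
      expect_equal(si[[f]], s0[[f]], tolerance = 1e-9)
  }
  ## the constant-lambda instantaneous optimum differs from the acclimated
  ## setpoint (the instantaneous water price is below the long-run marginal
  ## cost), so step 2 excurses before the week-scale step restores it
  expect_gt(tl$steps[[3]]$gs, s0$gs)
  expect_equal(tl$steps[[4]]$gs, s0$gs, tolerance = 1e-9)
})

test_that("with co-acclimating Jmax, step 4 equals the fresh optimum at the new environment", {
  cs <- photo_constants()
  set.seed(11)
  for (i in 1:4) {
    env1 <- ref_env(ca_ppm = 400 * runif(1, 1 / 3, 3),
                    vpd = 1000 * runif(1, 1 / 3, 3))
    tl <- run_scenario(ref_env(), env1, cs, jmax_acclimate = TRUE)
    fresh <- initial_state(env1, cs)
    s4 <- tl$steps[[5]]
    for (f in names(fresh))
      expect_equal(s4[[f]], fresh[[f]], tolerance = 1e-4)
  }
  ## with frozen Jmax the optimality axes still both return to their targets
  tl <- run_scenario(ref_env(), ref_env(ca_ppm = 800), cs)
  fresh <- initial_state(ref_env(ca_ppm = 800), cs)
  expect_equal(tl$steps[[5]]$ci, fresh$ci, tolerance = 1e-6)
  expect_equal(tl$steps[[5]]$vcmax, fresh$vcmax, tolerance = 1e-6)
  expect_equal(tl$steps[[5]]$ratio_ci, 1, tolerance = 1e-9)
  expect_equal(tl$steps[[5]]$ratio_gs, cs$gamma_ratio, tolerance = 1e-12)
})

test_that("temperature or light perturbations are rejected with a clear message", {
  expect_error(run_scenario(ref_env(), ref_env(temp_c = 26)), "temp_c")
  expect_error(run_scenario(ref_env(), ref_env(ppfd = 900)), "ppfd")
})

test_that("normalization bounds every trait series in [0, 1] with maximum exactly 1", {
  tl <- normalize_timelapse(run_scenario(ref_env(), ref_env(ca_ppm = 800)))
  tab <- tl$table
  for (tr in unique(tab$trait)) {
    v <- tab$normalized_value[tab$trait == tr]
    expect_true(all(v >= 0 & v <= 1))
    expect_identical(max(v), 1)
  }
  ## assimilation peaks at the instantaneous release, then declines slightly
  a_norm <- tab$normalized_value[tab$trait == "a_leaf"]
  expect_identical(which.max(a_norm), 2L)
  expect_true(all(a_norm[3:5] < 1))
  ## a constant series normalizes to all ones
  tl0 <- normalize_timelapse(run_scenario(ref_env(), ref_env()))
  vc <- tl0$table$normalized_value[tl0$table$trait == "vcmax"]
  expect_equal(vc, rep(1, 5))
})

test_that("percent changes are computed on full-precision values", {
  tl <- run_scenario(ref_env(), ref_env(ca_ppm = 800))
  pc <- percent_changes(tl)
  for (tr in c("gs", "vcmax", "a_leaf")) {
    v <- vapply(tl$steps, `[[`, numeric(1), tr)
    expect_equal(pc$pct_change[pc$trait == tr], 100 * (v[-1] - v[-5]) / v[-5])
  }
  ## null scenario: all changes are zero except the documented gs excursion
  pc0 <- percent_changes(run_scenario(ref_env(), ref_env()))
  expect_equal(pc0$pct_change[pc0$trait == "vcmax"], rep(0, 4))
})

test_that("identical configurations give bit-identical output tables", {
  t1 <- run_scenario(ref_env(), ref_env(ca_ppm = 800))
  t2 <- run_scenario(ref_env(), ref_env(ca_ppm = 800))
  expect_identical(t1$table, t2$table)
})
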