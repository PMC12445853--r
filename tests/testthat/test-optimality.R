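test_that("optimal chi hits the reference values and limits", {
  expect_equal(round(chi_optimal(ref_env(vpd = 1000))$chi, 2), 0.75)
  expect_equal(round(chi_optimal(ref_env(vpd = 2000))$chi, 2), 0.69)
  ## vanishing VPD: xi/(xi + sqrt(D)) -> 1, so chi -> 1
  expect_equal(chi_optimal(ref_env(vpd = 1e-10))$chi, 1, tolerance = 1e-6)
  co <- chi_optimal(ref_env())
  expect_gt(co$chi, co$gamma_star / ppm_to_pa(400))
  expect_lt(co$chi, 1)
  expect_gt(co$xi, 0)
  expect_gt(co$m, 0); expect_lt(co$m, 1)
})

test_that("chi decreases monotonically in VPD and in ambient CO2", {
  chi_d <- vapply(seq(200, 4000, length.out = 25),
                  function(d) chi_optimal(ref_env(vpd = d))$chi, numeric(1))
  expect_true(all(diff(chi_d) < 0))
  chi_ca <- vapply(seq(200, 1200, length.out = 25),
                   function(ca) chi_optimal(ref_env(ca_ppm = ca))$chi, numeric(1))
  expect_true(all(diff(chi_ca) < 0))
})

test_that("acclimated Vcmax satisfies coordination and the reported acclimation responses", {
  cs <- photo_constants()
  st <- acclimated_state(ref_env(), cs)
  ## co-limitation: Ac equals Aj at the acclimated ci with optimal Jmax
  j <- electron_transport(800, st$jmax, cs)
  res <- net_assimilation(st$ci, st$vcmax, j, 25, 101325, cs)
  expect_lt(abs(res$a_c - res$a_j), 1e-6)
  ## directional acclimation with magnitudes close to the reported ones
  v400 <- st$vcmax
  v800 <- acclimated_vcmax(ref_env(ca_ppm = 800), cs)
  v2k  <- acclimated_vcmax(ref_env(vpd = 2000), cs)
  expect_equal(100 * (v800 / v400 - 1), -23.4, tolerance = 0.015)
  expect_equal(100 * (v2k / v400 - 1), 3.6, tolerance = 0.015)
  expect_lt(v800, v400)   # higher ca -> lower Vcmax
  expect_gt(v2k, v400)    # higher VPD -> higher Vcmax
})

test_that("light-use-efficiency assimilation matches the coordinated FvCB rate", {
  cs <- photo_constants()
  expect_identical(lue_assimilation(ref_env(ppfd = 0), cs), 0)
  a <- lue_assimilation(ref_env(), cs)
  expect_equal(round(a, 1), 13.9)
  st <- acclimated_state(ref_env(), cs)
  j <- electron_transport(800, st$jmax, cs)
  expect_equal(a, net_assimilation(st$ci, st$vcmax, j, 25, 101325, cs)$a_net,
               tolerance = 1e-3)
  ## a dim environment that cannot pay the Jmax maintenance cost returns 0
  expect_warning(a0 <- lue_assimilation(ref_env(ppfd = 1e-3),
                                        photo_constants(c_jmax = 0.2)),
                 "maintenance cost")
  expect_identical(a0, 0)
})

test_that("instantaneous stomatal optimum agrees with a grid-search oracle", {
  cs <- photo_constants()
  set.seed(7)
  for (i in 1:5) {
    env_i <- ref_env(ca_ppm = runif(1, 300, 900), vpd = runif(1, 500, 2500))
    st <- acclimated_state(ref_env(), cs)
    opt <- instantaneous_gs(env_i, st$vcmax, st$jmax, cs)
    oracle <- grid_instantaneous_gs(env_i, st$vcmax, st$jmax, cs,
                                    gs_grid = seq(0.01, 0.8, length.out = 20000L))
    expect_equal(opt$gs, oracle, tolerance = 1e-3)  # < 0.1 percent
    expect_gt(opt$ci, gamma_star(env_i$temp_c, env_i$patm, cs))
  }
})

test_that("a monotone objective is reported as a boundary optimum", {
  cs <- photo_constants()
  st <- acclimated_state(ref_env(), cs)
  ## zero water cost: opening further always pays, optimum at the bound
  expect_warning(instantaneous_gs(ref_env(), st$vcmax, st$jmax, cs,
                                  lambda = 0, gs_upper = 0.5),
                 "boundary")
})

test_that("acclimated gs reproduces the acclimated ci through the supply line", {
  cs <- photo_constants()
  for (env_i in list(ref_env(), ref_env(vpd = 2000), ref_env(ca_ppm = 800))) {
    st <- acclimated_state(env_i, cs)
    ci_back <- solve_ci(st$gs, env_i, st$vcmax, st$jmax, cs, demand = "rubp")
    expect_equal(ci_back, st$ci, tolerance = 0.05)
  }
})

test_that("re-running the acclimation operators on an acclimated state changes nothing", {
  cs <- photo_constants()
  env <- ref_env(vpd = 1700, ca_ppm = 550)
  st <- acclimated_state(env, cs)
  st2 <- acclimated_state(env, cs)
  expect_identical(st, st2)
  expect_equal(acclimated_vcmax(env, cs), st$vcmax)
  expect_equal(acclimated_gs(env, cs), st$gs)
  expect_equal(lue_assimilation(env, cs), st$a_leaf)
})
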