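test_that("assimilation limits behave at the compensation point and dark", {
  p <- fvcb_params(Vcmax25 = 50, Jmax25 = 100, Rd25 = 1.3)
  # at 25 C the kinetic constants equal their reference values
  expect_equal(fvcb_assimilation(42.75, 1500, 25, p), -1.3, tolerance = 1e-9)
  expect_equal(fvcb_assimilation(300, 0, 25, p), -1.3, tolerance = 1e-9)
})

test_that("Rubisco-limited assimilation matches hand arithmetic", {
  p <- fvcb_params(Vcmax25 = 50, Jmax25 = 300, Rd25 = 1)
  # 50 * (300 - 42.75) / (300 + 404.9 * (1 + 210/278.4)) - 1
  expect_equal(fvcb_assimilation(300, 5000, 25, p), 11.7306,
               tolerance = 1e-3)
  expect_error(fvcb_assimilation(-5, 1500, 25, p), "Ci")
})

test_that("assimilation is continuous and non-decreasing above Gamma*", {
  p <- fvcb_params()
  Ci <- seq(45, 1500, by = 1)
  for (PAR in c(50, 400, 1500)) {
    A <- fvcb_assimilation(Ci, PAR, 25, p)
    expect_true(all(diff(A) > -1e-10))
    expect_lt(max(abs(diff(A))), 0.5) # no jumps at the limitation switch
  }
})

test_that("coupled solution satisfies demand-supply closure", {
  p <- fvcb_params(Vcmax25 = 50, Rd25 = 1)
  spec <- stomatal_spec("BBD", m = 9, g0 = 0.0055, gmin = 0.0055)
  st <- solve_coupled(spec, p, list(PAR = 500, T = 25, Ca = 400, RH = 0.5))
  expect_lt(abs(st$A - (st$gs / 1.6) * (400 - st$Ci)), 1e-6)
  expect_gt(st$Ci, 0)
  # in the dark the floor carries the (respiring) leaf: Ci above ambient
  st0 <- solve_coupled(spec, p, list(PAR = 0, T = 25, Ca = 400, RH = 0.5))
  expect_equal(st0$gs, 0.0055)
  expect_gt(st0$Ci, 400)
  expect_lt(abs(st0$A - (st0$gs / 1.6) * (400 - st0$Ci)), 1e-6)
})

test_that("solver agrees with the brute-force grid oracle", {
  p <- fvcb_params(Vcmax25 = 50, Rd25 = 1)
  spec <- stomatal_spec("BBD", m = 9, g0 = 0.0055, gmin = 0.0055)
  env <- list(PAR = 500, T = 25, Ca = 400, RH = 0.5)
  st <- solve_coupled(spec, p, env)
  expect_lt(abs(st$Ci - grid_scan_ci(spec, p, env)), 0.02)
})

test_that("coupled residual has a single sign change on the bracket", {
  set.seed(31)
  for (i in 1:200) {
    p <- fvcb_params(Vcmax25 = runif(1, 20, 120),
                     Jmax25 = runif(1, 50, 250),
                     Rd25 = runif(1, 0.3, 2.5))
    spec <- stomatal_spec("BBD", m = runif(1, 3, 15),
                          g0 = runif(1, 0.002, 0.02),
                          gmin = runif(1, 0.002, 0.02))
    env <- list(PAR = runif(1, 100, 1500), T = runif(1, 10, 40),
                Ca = runif(1, 300, 800), RH = runif(1, 0.2, 0.8))
    Ci <- seq(1, 3 * env$Ca, by = 1)
    A <- fvcb_assimilation(Ci, env$PAR, env$T, p)
    gs <- pmax(predict_gs(spec, A, env$RH, env$Ca), 1e-9)
    resid <- A - (gs / 1.6) * (env$Ca - Ci)
    expect_equal(sum(diff(sign(resid)) != 0), 1)
  }
})

test_that("extreme floors drive the expected diffusion limits", {
  p <- fvcb_params()
  # a huge floor removes the supply limitation: Ci approaches Ca
  open <- stomatal_spec("BBD", m = 9, g0 = 50, gmin = 50)
  st <- solve_coupled(open, p, list(PAR = 1500, T = 25, Ca = 400, RH = 0.5))
  expect_lt(400 - st$Ci, 1)
  # a tiny floor on a respiring leaf: solution found on the expanded
  # bracket, far above ambient
  tiny <- stomatal_spec("BBD", m = 9, g0 = 6e-4, gmin = 6e-4)
  st2 <- solve_coupled(tiny, p, list(PAR = 0, T = 25, Ca = 400, RH = 0.5))
  expect_equal(st2$gs, 6e-4)
  expect_gt(st2$Ci, 1200)
  expect_lt(abs(st2$residual), 1e-6)
})

test_that("A/Ci fitting recovers generating parameters without noise", {
  p_true <- fvcb_params(Vcmax25 = 70, Jmax25 = 130, Rd25 = 1.2)
  curve <- gen_aci_curve(p_true, noise_sd = 0, seed = 5)
  f <- fit_aci(curve, fvcb_params())
  expect_lt(abs(f$params$Vcmax25 - 70) / 70, 0.01)
  expect_lt(abs(f$params$Jmax25 - 130) / 130, 0.01)
  expect_lt(abs(f$params$Rd25 - 1.2) / 1.2, 0.01)
  expect_false(f$ill_determined)
})

test_that("A/Ci fitting identity holds across random parameter draws", {
  set.seed(41)
  for (i in 1:10) {
    # Jmax co-varies with Vcmax (empirical ratio ~1.6-2.2) so the curve
    # exposes both limitation regimes and both rates are identifiable
    Vc <- runif(1, 30, 110)
    p_true <- fvcb_params(Vcmax25 = Vc,
                          Jmax25 = Vc * runif(1, 1.6, 2.2),
                          Rd25 = runif(1, 0.5, 2))
    curve <- gen_aci_curve(p_true, noise_sd = 0, seed = i)
    f <- fit_aci(curve, fvcb_params())
    expect_lt(abs(f$params$Vcmax25 - p_true$Vcmax25) / p_true$Vcmax25, 0.02)
    expect_lt(abs(f$params$Jmax25 - p_true$Jmax25) / p_true$Jmax25, 0.02)
  }
})

test_that("A/Ci fitting is modestly biased under measurement noise", {
  p_true <- fvcb_params(Vcmax25 = 60, Jmax25 = 120, Rd25 = 1)
  err <- vapply(1:15, function(s) {
    curve <- gen_aci_curve(p_true, noise_sd = 0.5, seed = s)
    f <- fit_aci(curve, fvcb_params())
    (f$params$Vcmax25 - 60) / 60
  }, numeric(1))
  expect_lt(abs(median(err)), 0.05)
})

test_that("a curve with only high-Ci points is flagged ill-determined", {
  p_true <- fvcb_params()
  curve <- gen_aci_curve(p_true, noise_sd = 0, seed = 2)
  high <- curve[curve$Ci_umol > 600, ]
  expect_true(nrow(high) >= 3)
  high <- rbind(high, high) # >= 6 points, all transport-limited
  expect_warning(f <- fit_aci(high, fvcb_params()), "ill-determined")
  expect_true(f$ill_determined)
})

test_that("sweeps preserve the floor ordering of Ci and transpiration", {
  # severely water-stressed sun leaf: assimilation ~1 umol m-2 s-1 at
  # growth light, so the conductance floor governs the gas exchange
  p <- fvcb_params(Vcmax25 = 15, Jmax25 = 30, Rd25 = 1)
  specs <- list(
    gd = stomatal_spec("BBD", m = 9, g0 = 0.0203, gmin = 0.0203),
    gmld = stomatal_spec("BBD", m = 9, g0 = 0.0055, gmin = 0.0055))
  par_tab <- simulate_response(specs, p, "par", grid = seq(50, 1500, 100),
                               env = list(T = 25, Ca = 400, RH = 0.3,
                                          P = 101.325))
  expect_true(all(is.na(par_tab$error)))
  ci_gd <- par_tab$Ci[par_tab$spec == "gd"]
  ci_gmld <- par_tab$Ci[par_tab$spec == "gmld"]
  expect_true(all(ci_gd >= ci_gmld - 1e-8))
  # identical specs give identical curves
  dup <- simulate_response(list(a = specs$gd, b = specs$gd), p, "par",
                           grid = c(100, 200, 800))
  expect_equal(dup$Ci[dup$spec == "a"], dup$Ci[dup$spec == "b"])
})

test_that("the Ci ordering inverts for a net-respiring leaf", {
  # below the light-compensation point A < 0: the balance point sits
  # above ambient CO2 and a LARGER floor then pins Ci CLOSER to Ca, so
  # the floor ordering of Ci only holds for an assimilating leaf
  p <- fvcb_params(Vcmax25 = 15, Jmax25 = 30, Rd25 = 1)
  big <- stomatal_spec("BBD", m = 9, g0 = 0.0203, gmin = 0.0203)
  small <- stomatal_spec("BBD", m = 9, g0 = 0.0055, gmin = 0.0055)
  env <- list(PAR = 0, T = 25, Ca = 400, RH = 0.3)
  ci_big <- solve_coupled(big, p, env)$Ci
  ci_small <- solve_coupled(small, p, env)$Ci
  expect_gt(ci_big, 400)
  expect_gt(ci_small, ci_big)
})
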