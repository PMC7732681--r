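test_that("predicted conductance honours each form's floor rule", {
  # floored form at zero assimilation returns the measured floor
  bbd <- stomatal_spec("BBD", m = 10, g0 = 0.0055, gmin = 0.002)
  expect_equal(predict_gs(bbd, A = 0, RH = 0.3, Ca = 400), 0.0055)
  # max-of-floors vs min-of-floors on the same inputs (index term 0.003)
  bbmin <- stomatal_spec("BB_MIN", m = 10, g0 = 0.0055, gmin = 0.002)
  A <- 0.003 * 400 / (10 * 0.5) # makes m*A*RH/Ca = 0.003
  expect_equal(predict_gs(bbd, A, 0.5, 400), 0.0055)
  expect_equal(predict_gs(bbmin, A, 0.5, 400), 0.003)
  # additive form, direct arithmetic
  bb <- stomatal_spec("BB", m = 10, gint = 0.0089)
  expect_equal(predict_gs(bb, 10, 0.5, 400), 0.1339)
  # additive form can drop below its intercept under respiration
  expect_lt(predict_gs(bb, -2, 0.5, 400), 0.0089)
  expect_error(predict_gs(bb, 10, 0.5, 0), "Ca")
})

test_that("spec constructor rejects incomplete or invalid forms", {
  expect_error(stomatal_spec("BBD", m = 9, g0 = 0.005), "g0 and gmin")
  expect_error(stomatal_spec("BB_MEAS", m = 9), "gint")
  expect_error(stomatal_spec("BBD", m = -1, g0 = 1e-3, gmin = 1e-3), "m")
  expect_error(stomatal_spec("BBD", m = 9, g0 = -1e-3, gmin = 1e-3),
               "floors")
})

test_that("least-squares AIC matches direct arithmetic", {
  expect_equal(aic(RSS = 30, n = 30, k = 1), 4)
  expect_equal(aic(0.0368, 30, 1), 30 * log(0.0368 / 30) + 4,
               tolerance = 1e-12)
  expect_equal(aic(0.0368, 30, 1), -197.104, tolerance = 1e-3)
  # unit rescaling shifts every AIC by the same constant: ranking invariant
  shift <- aic(0.0368 * 1e6, 30, 1) - aic(0.0368, 30, 1)
  expect_equal(shift, 2 * 30 * log(1000), tolerance = 1e-9)
  expect_warning(expect_equal(aic(0, 10, 1), -Inf), "degenerate")
})

test_that("delta-AIC and the 2-unit plausibility rule", {
  d <- delta_aic(c(-106.88, -106.6))
  expect_equal(d$dAIC, c(0, 0.28))
  expect_false(any(d$more_plausible)) # within 2 units: indistinguishable
  d2 <- delta_aic(c(-110, -106, -100))
  expect_equal(d2$dAIC, c(0, 4, 10))
  expect_equal(d2$more_plausible, c(TRUE, FALSE, FALSE))
  expect_equal(delta_aic(-5)$dAIC, 0)
})

test_that("noiseless linear records are recovered exactly by the BB fit", {
  spec <- stomatal_spec("BB", m = 9.3, gint = 0.011)
  rec <- make_bb_records(spec, A = seq(-1, 15, length.out = 40),
                         RH = runif(40, 0.2, 0.6))
  f <- fit_model(rec, "BB")
  expect_equal(f$spec$m, 9.3, tolerance = 1e-8)
  expect_equal(f$spec$gint, 0.011, tolerance = 1e-10)
  expect_equal(f$k, 2)
  expect_lt(f$RSS, 1e-20)
})

test_that("fixed-intercept fit recovers the slope through the origin", {
  spec <- stomatal_spec("BB_MEAS", m = 7.7, gint = 0.0055)
  rec <- make_bb_records(spec, A = seq(0.5, 12, length.out = 30))
  # exact data: zero RSS is flagged as a degenerate AIC
  expect_warning(f <- fit_model(rec, "BB_MEAS", gint = 0.0055),
                 "degenerate")
  expect_equal(f$spec$m, 7.7, tolerance = 1e-8)
  expect_equal(f$k, 1)
})

test_that("floored fits recover the slope and are locally optimal", {
  set.seed(7)
  truth <- stomatal_spec("BBD", m = 9, g0 = 0.0055, gmin = 0.0055)
  A <- c(runif(100, -0.5, 1), runif(100, 2, 15))
  rec <- make_bb_records(truth, A, RH = runif(200, 0.25, 0.35))
  rec$gs_mol <- rec$gs_mol + rnorm(200, 0, 0.005)
  f <- fit_model(rec, "BBD", g0 = 0.0055, gmin = 0.0055)
  expect_lt(abs(f$spec$m - 9) / 9, 0.05)
  # local optimality of the returned slope on a +-10% grid
  x <- rec$A_umol * rec$RH_frac / rec$Ca_umol
  rss_at <- function(m) sum((rec$gs_mol - pmax(0.0055, m * x))^2)
  expect_lte(f$RSS, rss_at(f$spec$m * 0.9))
  expect_lte(f$RSS, rss_at(f$spec$m * 1.1))
})

test_that("max-floor and min-floor fits coincide when g0 equals gmin", {
  set.seed(8)
  truth <- stomatal_spec("BBD", m = 8, g0 = 0.004, gmin = 0.004)
  rec <- make_bb_records(truth, runif(60, -1, 12), RH = 0.3)
  rec$gs_mol <- rec$gs_mol + rnorm(60, 0, 0.003)
  f_max <- fit_model(rec, "BBD", g0 = 0.004, gmin = 0.004)
  f_min <- fit_model(rec, "BB_MIN", g0 = 0.004, gmin = 0.004)
  expect_equal(f_max$spec$m, f_min$spec$m)
  expect_equal(f_max$RSS, f_min$RSS)
  expect_equal(
    predict_gs(f_max$spec, 5, 0.3, 400),
    predict_gs(f_min$spec, 5, 0.3, 400))
})

test_that("degenerate fitting inputs raise informative errors", {
  truth <- stomatal_spec("BBD", m = 9, g0 = 0.05, gmin = 0.05)
  # every record sits on the floor: slope unidentifiable
  rec <- make_bb_records(truth, A = runif(20, -0.5, 0.5), RH = 0.3)
  expect_error(fit_model(rec, "BBD", g0 = 0.05, gmin = 0.05),
               "unidentifiable")
  expect_error(fit_model(rec[1:2, ], "BB"), ">= 3")
})

test_that("observed-vs-predicted regression matches the closed-form OLS", {
  obs <- c(0.01, 0.03, 0.02, 0.05, 0.041, 0.066)
  pred <- c(0.012, 0.028, 0.025, 0.047, 0.040, 0.060)
  r <- obs_pred_regression(obs, pred)
  # textbook formulas as the independent oracle
  b <- sum((pred - mean(pred)) * (obs - mean(obs))) /
    sum((pred - mean(pred))^2)
  a <- mean(obs) - b * mean(pred)
  expect_equal(r$slope, b, tolerance = 1e-10)
  expect_equal(r$intercept, a, tolerance = 1e-10)
  expect_equal(r$r_squared, cor(obs, pred)^2, tolerance = 1e-10)

  ident <- obs_pred_regression(obs, obs)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-15)
  expect_equal(ident$r_squared, 1)
  shifted <- obs_pred_regression(obs + 0.01, obs)
  expect_equal(shifted$slope, 1)
  expect_equal(shifted$intercept, 0.01)
  expect_error(obs_pred_regression(obs, rep(0.03, 6)), "variance")
})

test_that("model ranking refuses fits from different record sets", {
  spec <- stomatal_spec("BB", m = 9, gint = 0.009)
  rec1 <- make_bb_records(spec, seq(1, 10))
  rec2 <- make_bb_records(spec, seq(2, 11))
  rec1$gs_mol <- rec1$gs_mol + rnorm(10, 0, 1e-3)
  rec2$gs_mol <- rec2$gs_mol + rnorm(10, 0, 1e-3)
  f1 <- fit_model(rec1, "BB")
  f2 <- fit_model(rec2, "BB_MEAS", gint = 0.009)
  expect_error(compare_models(list(f1, f2)), "not comparable")
  f3 <- fit_model(rec1, "BB_MEAS", gint = 0.009)
  tab <- compare_models(list(f1, f3))
  expect_equal(min(tab$dAIC), 0)
  expect_equal(nrow(tab), 2)
})

test_that("growth-light calibration transfers to swapped-light validation", {
  d <- bbd_design(replicates = 10)
  rec <- gen_gas_exchange(d, seed = 21)
  cal <- rec[rec$role == "growth", ]
  val <- rec[rec$role == "swapped", ]
  f <- fit_model(cal, "BBD", g0 = 0.0055, gmin = 0.0055)
  pred <- predict_gs(f$spec, val$A_umol, val$RH_frac, val$Ca_umol)
  r <- obs_pred_regression(val$gs_mol, pred)
  expect_gte(r$r_squared, 0)
  expect_lte(r$r_squared, 1)
  expect_equal(r$slope, 1, tolerance = 0.15) # true model transfers
})

test_that("support for the generating floored model grows with sample size", {
  win_fraction <- function(replicates, seeds) {
    wins <- vapply(seeds, function(s) {
      d <- bbd_design(replicates = replicates)
      cal <- gen_gas_exchange(d, seed = s, roles = "growth")
      fits <- list(
        fit_model(cal, "BBD", g0 = 0.0055, gmin = 0.0055),
        fit_model(cal, "BB"),
        fit_model(cal, "BB_MEAS", gint = 0.0055))
      a <- vapply(fits, `[[`, numeric(1), "AIC")
      all(a[-1] - a[1] >= 2)
    }, logical(1))
    mean(wins)
  }
  small <- win_fraction(8, 1:12)   # ~48 calibration records
  large <- win_fraction(50, 1:12)  # ~300 calibration records
  expect_gte(large, small)
  expect_gte(large, 0.9)
})
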