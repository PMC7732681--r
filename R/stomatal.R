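#' Stomatal model specification
#'
#' A member of the Ball-Berry family with its parameters. Four forms are
#' supported, differing in how residual conductance enters:
#' \describe{
#'   \item{`BB`}{\eqn{g_s = g_{int} + m \, A \, RH / C_a}, both
#'     parameters fitted by least squares;}
#'   \item{`BB_MEAS`}{same equation but \eqn{g_{int}} fixed at a measured
#'     residual conductance, only the slope fitted;}
#'   \item{`BBD`}{\eqn{g_s = \max[\max(g_0, g_{min}),\; m A \, RH / C_a]},
#'     the measured floor acting as an absolute minimum;}
#'   \item{`BB_MIN`}{\eqn{g_s = \max[\min(g_0, g_{min}),\; m A \, RH / C_a]},
#'     taking the smaller of the two floor candidates instead.}
#' }
#' All conductances are in mol m-2 s-1 internally; measured floors are
#' typically quoted in mmol m-2 s-1 and should be converted with
#' [mmol_to_mol()] at this boundary.
#'
#' @param form One of `"BB"`, `"BBD"`, `"BB_MEAS"`, `"BB_MIN"`.
#' @param m Slope (dimensionless), >= 0. May be `NA` before fitting.
#' @param gint Intercept (mol m-2 s-1); required for `BB_MEAS`, fitted
#'   for `BB`.
#' @param g0 Floor candidate from the P0 x shade cell (mol m-2 s-1);
#'   required for `BBD`/`BB_MIN`.
#' @param gmin Floor candidate from the P80 x sun cell (mol m-2 s-1);
#'   required for `BBD`/`BB_MIN`.
#' @param floor_source Provenance tag for the floors: `"MLD"`,
#'   `"nocturnal"` or `"daytime"`.
#' @return An object of class `stomatal_spec`.
#' @examples
#' stomatal_spec("BBD", m = 9, g0 = 0.0055, gmin = 0.0055)
#' @export
stomatal_spec <- function(form = c("BB", "BBD", "BB_MEAS", "BB_MIN"),
                          m = NA_real_, gint = NULL, g0 = NULL, gmin = NULL,
                          floor_source = NA_character_) {
  form <- match.arg(form)
  if (!is.na(m) && m < 0) stop("stomatal_spec: m must be >= 0", call. = FALSE)
  if (form %in% c("BBD", "BB_MIN")) {
    if (is.null(g0) || is.null(gmin)) {
      stop("stomatal_spec: form ", form, " requires both g0 and gmin",
           call. = FALSE)
    }
    if (g0 < 0 || gmin < 0) {
      stop("stomatal_spec: floors must be >= 0", call. = FALSE)
    }
  }
  if (form == "BB_MEAS" && is.null(gint)) {
    stop("stomatal_spec: form BB_MEAS requires a measured gint",
         call. = FALSE)
  }
  structure(list(form = form, m = m, gint = gint, g0 = g0, gmin = gmin,
                 floor_source = floor_source),
            class = "stomatal_spec")
}

# effective floor of a spec (mol m-2 s-1); NA for the additive forms
spec_floor <- function(spec) {
  switch(spec$form,
    BBD = max(spec$g0, spec$gmin),
    BB_MIN = min(spec$g0, spec$gmin),
    NA_real_
  )
}

#' Predict stomatal conductance
#'
#' Evaluates a [stomatal_spec()] at the Ball-Berry index
#' \eqn{x = A \, RH / C_a}. The additive forms may predict below their
#' intercept when `A` is negative (respiration); the floored forms cannot
#' drop below their floor.
#'
#' @param spec A [stomatal_spec()] with `m` set.
#' @param A Net assimilation (umol m-2 s-1).
#' @param RH Relative humidity (fraction).
#' @param Ca Ambient CO2 (umol mol-1), > 0.
#' @return Stomatal conductance to water (mol m-2 s-1), vectorized over
#'   `A`, `RH`, `Ca`.
#' @export
predict_gs <- function(spec, A, RH, Ca) {
  stopifnot(inherits(spec, "stomatal_spec"))
  if (any(Ca <= 0)) stop("predict_gs: Ca must be > 0", call. = FALSE)
  if (is.na(spec$m)) {
    stop("predict_gs: spec has no slope m (unfitted?)", call. = FALSE)
  }
  bb <- spec$m * A * RH / Ca
  switch(spec$form,
    BB = ,
    BB_MEAS = spec$gint + bb,
    BBD = pmax(spec_floor(spec), bb),
    BB_MIN = pmax(spec_floor(spec), bb)
  )
}

#' Gaussian least-squares AIC
#'
#' \eqn{AIC = n \ln(RSS/n) + 2(k+1)}, the error variance counted as one
#' estimated parameter. Smaller is better; differences, not levels, carry
#' the meaning (a unit change of `gs` shifts every model's AIC by the
#' same additive constant).
#'
#' @param RSS Residual sum of squares, > 0 (`RSS = 0` returns `-Inf` with
#'   a degenerate-fit warning).
#' @param n Number of observations, > k.
#' @param k Number of fitted model parameters, >= 1.
#' @return The AIC value.
#' @export
aic <- function(RSS, n, k) {
  stopifnot(is.numeric(RSS), n > k, k >= 1)
  if (RSS < 0) stop("aic: RSS must be >= 0", call. = FALSE)
  if (RSS == 0) {
    warning("aic: RSS = 0, degenerate fit; returning -Inf", call. = FALSE)
    return(-Inf)
  }
  n * log(RSS / n) + 2 * (k + 1)
}

#' Observed-versus-predicted regression diagnostics
#'
#' Simple linear regression with the observations as response and the
#' model predictions as regressor. An unbiased model has slope 1 and
#' intercept 0; departures are flagged when the estimate differs from its
#' reference by more than twice its standard error.
#'
#' @param observed,predicted Equal-length numeric vectors, >= 3 pairs.
#' @return A list: `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `r_squared`, and logical flags `slope_differs_from_1`,
#'   `intercept_differs_from_0`.
#' @export
obs_pred_regression <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::var(predicted) <= 0) {
    stop("obs_pred_regression: zero variance in predictions; slope undefined",
         call. = FALSE)
  }
  fit <- stats::lm(observed ~ predicted)
  cf <- stats::coef(fit)
  # closed-form SEs: quiet on degenerate (perfect-prediction) input
  n <- length(observed)
  rss <- sum(stats::resid(fit)^2)
  sxx <- sum((predicted - mean(predicted))^2)
  s2 <- rss / (n - 2)
  se <- c(sqrt(s2 * (1 / n + mean(predicted)^2 / sxx)), sqrt(s2 / sxx))
  r2 <- stats::cor(observed, predicted)^2
  list(slope = unname(cf[2]), slope_se = unname(se[2]),
       intercept = unname(cf[1]), intercept_se = unname(se[1]),
       r_squared = r2,
       slope_differs_from_1 = abs(cf[[2]] - 1) > 2 * se[[2]],
       intercept_differs_from_0 = abs(cf[[1]]) > 2 * se[[1]])
}

# RSS of a floored predictor at slope m
floored_rss <- function(m, floor, x, gs) {
  sum((gs - pmax(floor, m * x))^2)
}

# deterministic 1-D minimisation of the piecewise-smooth RSS(m):
# 500-point bracketing grid on [lo, hi] then golden-section to tol
golden_min_m <- function(floor, x, gs, lo = 0, hi = 50, tol = 1e-8) {
  grid <- seq(lo, hi, length.out = 500)
  rss <- vapply(grid, floored_rss, numeric(1), floor = floor, x = x, gs = gs)
  i <- which.min(rss)
  a <- grid[max(1, i - 1)]
  b <- grid[min(length(grid), i + 1)]
  phi <- (sqrt(5) - 1) / 2
  c1 <- b - phi * (b - a)
  c2 <- a + phi * (b - a)
  f1 <- floored_rss(c1, floor, x, gs)
  f2 <- floored_rss(c2, floor, x, gs)
  while (b - a > tol) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a)
      f1 <- floored_rss(c1, floor, x, gs)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a)
      f2 <- floored_rss(c2, floor, x, gs)
    }
  }
  (a + b) / 2
}

#' Fit a Ball-Berry-family model to gas-exchange records
#'
#' Calibrates one model form on a set of records (typically those
#' measured under growth light). `BB` is a closed-form ordinary
#' least-squares fit of `gs` on the index \eqn{x = A\,RH/C_a}; `BB_MEAS`
#' fits the slope only, through the origin of \eqn{(g_s - g_{int})} on
#' `x`; the floored forms (`BBD`, `BB_MIN`) minimise the residual sum of
#' squares of the kinked predictor over the slope by a deterministic
#' bracketing-grid plus golden-section search on m in \[0, 50\]
#' (tolerance 1e-8). Records with negative `A` are retained: the floor
#' absorbs them in the floored forms, and the additive forms may predict
#' below their intercept, as their equation dictates.
#'
#' Fixed floors and measured intercepts count as measurements, not
#' fitted parameters, so k = 2 for `BB` and k = 1 otherwise (the error
#' variance is accounted inside [aic()]).
#'
#' @param records data.frame of gas-exchange observations with columns
#'   `A_umol`, `gs_mol`, `Ca_umol`, `RH_frac` (as produced by
#'   [gen_gas_exchange()] or [read_gas_exchange_table()]); >= 3 rows.
#' @param form Model form; see [stomatal_spec()].
#' @param g0,gmin Fixed floor candidates (mol m-2 s-1) for
#'   `BBD`/`BB_MIN`, usually from [assign_g0_gmin()] via [mmol_to_mol()].
#' @param gint Fixed measured intercept (mol m-2 s-1) for `BB_MEAS`.
#' @param floor_source Provenance tag stored in the returned spec.
#' @return An object of class `stomatal_fit`: `spec` (fitted
#'   [stomatal_spec()]), `n`, `k`, `RSS`, `AIC`, `obs_pred`
#'   ([obs_pred_regression()] on the calibration records), `gint_se`
#'   (BB only), `records_id` (checksum used to refuse cross-data-set
#'   AIC comparisons).
#' @export
fit_model <- function(records, form = c("BB", "BBD", "BB_MEAS", "BB_MIN"),
                      g0 = NULL, gmin = NULL, gint = NULL,
                      floor_source = NA_character_) {
  form <- match.arg(form)
  need <- c("A_umol", "gs_mol", "Ca_umol", "RH_frac")
  if (!all(need %in% names(records))) {
    stop("fit_model: records must have columns ",
         paste(setdiff(need, names(records)), collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  if (n < 3) stop("fit_model: need >= 3 records", call. = FALSE)
  x <- records$A_umol * records$RH_frac / records$Ca_umol
  gs <- records$gs_mol
  gint_se <- NA_real_

  if (form == "BB") {
    k <- 2L
    ols <- stats::lm(gs ~ x)
    cf <- stats::coef(ols)
    spec <- stomatal_spec("BB", m = unname(cf[2]), gint = unname(cf[1]))
    s2 <- sum(stats::resid(ols)^2) / (n - 2)
    gint_se <- sqrt(s2 * (1 / n + mean(x)^2 / sum((x - mean(x))^2)))
    pred <- predict_gs(spec, records$A_umol, records$RH_frac, records$Ca_umol)
  } else if (form == "BB_MEAS") {
    if (is.null(gint)) stop("fit_model: BB_MEAS requires gint", call. = FALSE)
    k <- 1L
    y <- gs - gint
    m_hat <- sum(x * y) / sum(x * x)
    spec <- stomatal_spec("BB_MEAS", m = m_hat, gint = gint,
                          floor_source = floor_source)
    pred <- predict_gs(spec, records$A_umol, records$RH_frac, records$Ca_umol)
  } else {
    if (is.null(g0) || is.null(gmin)) {
      stop("fit_model: ", form, " requires g0 and gmin", call. = FALSE)
    }
    k <- 1L
    floor <- if (form == "BBD") max(g0, gmin) else min(g0, gmin)
    if (all(floor >= 50 * x)) {
      stop("fit_model: all records in the floor-active regime; ",
           "slope m is unidentifiable", call. = FALSE)
    }
    m_hat <- golden_min_m(floor, x, gs)
    spec <- stomatal_spec(form, m = m_hat, g0 = g0, gmin = gmin,
                          floor_source = floor_source)
    pred <- predict_gs(spec, records$A_umol, records$RH_frac, records$Ca_umol)
  }
  if (n <= k) stop("fit_model: n <= k, no residual degrees of freedom",
                   call. = FALSE)
  RSS <- sum((gs - pred)^2)
  structure(list(
    spec = spec, n = n, k = k, RSS = RSS,
    AIC = aic(RSS, n, k),
    obs_pred = obs_pred_regression(gs, pred),
    gint_se = gint_se,
    records_id = records_checksum(records)
  ), class = "stomatal_fit")
}

# order-insensitive fingerprint of the fitting data
records_checksum <- function(records) {
  signif(sum(records$gs_mol) + sum(records$A_umol) + nrow(records), 12)
}

#' Delta-AIC from raw AIC values
#'
#' \eqn{\Delta AIC_i = AIC_i - \min_j AIC_j}. A model is flagged "more
#' plausible" than the rest only when every competitor's AIC exceeds its
#' own by at least 2 units.
#'
#' @param aics Numeric vector of AIC values on the same data.
#' @return data.frame with columns `AIC`, `dAIC`, `more_plausible`.
#' @export
delta_aic <- function(aics) {
  stopifnot(is.numeric(aics), length(aics) >= 1)
  d <- aics - min(aics)
  plaus <- vapply(seq_along(aics), function(i) {
    others <- aics[-i]
    length(others) == 0 || all(others - aics[i] >= 2)
  }, logical(1))
  data.frame(AIC = aics, dAIC = d, more_plausible = plaus)
}

#' Rank competing stomatal model fits by AIC
#'
#' Computes delta-AIC across fits of different forms to the same records
#' and flags the forms that are distinguishably more plausible (every
#' rival at least 2 AIC units worse). Refuses to compare fits performed
#' on different record sets.
#'
#' @param fits A list of [fit_model()] results on identical records.
#' @return data.frame, one row per fit, sorted by AIC: `form`,
#'   `floor_source`, `n`, `k`, `RSS`, `AIC`, `dAIC`, `more_plausible`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  if (!all(vapply(fits, inherits, logical(1), "stomatal_fit"))) {
    stop("compare_models: fits must be stomatal_fit objects", call. = FALSE)
  }
  ids <- vapply(fits, `[[`, numeric(1), "records_id")
  if (length(unique(ids)) != 1) {
    stop("compare_models: fits were made on different record sets; ",
         "AIC values are not comparable", call. = FALSE)
  }
  tab <- data.frame(
    form = vapply(fits, function(f) f$spec$form, character(1)),
    floor_source = vapply(fits, function(f)
      as.character(f$spec$floor_source %||% NA_character_), character(1)),
    n = vapply(fits, `[[`, numeric(1), "n"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    RSS = vapply(fits, `[[`, numeric(1), "RSS")
  )
  tab <- cbind(tab, delta_aic(vapply(fits, `[[`, numeric(1), "AIC")))
  tab[order(tab$AIC), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
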