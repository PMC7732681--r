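#' Detached-leaf drying series
#'
#' A timed weighing log of one detached leaf: the raw material for the
#' mass-loss estimate of residual conductance. The petiole is assumed
#' sealed, so all mass loss is water lost through the leaf surface, and
#' the air state is taken constant over the drying period (when
#' per-weighing air states are available, pass their mean).
#'
#' @param times Seconds since detachment, strictly increasing, length >= 3.
#' @param masses Leaf fresh mass (g), positive, same length as `times`.
#' @param area Projected leaf area (m2), > 0.
#' @param air An [air_state()] for the drying environment.
#' @return An object of class `mass_loss_series`.
#' @export
mass_loss_series <- function(times, masses, area, air) {
  stopifnot(is.numeric(times), is.numeric(masses), inherits(air, "air_state"))
  if (length(times) < 3 || length(times) != length(masses)) {
    stop("mass_loss_series: need >= 3 (time, mass) pairs of equal length",
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("mass_loss_series: times must be strictly increasing", call. = FALSE)
  }
  if (any(masses <= 0)) {
    stop("mass_loss_series: masses must be positive (g)", call. = FALSE)
  }
  if (!is.numeric(area) || length(area) != 1 || area <= 0) {
    stop("mass_loss_series: area must be a positive scalar (m2)",
         call. = FALSE)
  }
  structure(list(times = times, masses = masses, area = area, air = air),
            class = "mass_loss_series")
}

# molar mass of water, g mol-1; leaf dry-mass change over 2 h is neglected
MOLAR_MASS_WATER <- 18.015

#' Water-loss flux from a drying curve
#'
#' Ordinary least-squares slope of mass against time over a selected
#' window, converted to a molar water flux per projected leaf area:
#' \eqn{E_{MLD} = -slope / (M_w \cdot area)} with \eqn{M_w} = 18.015
#' g mol-1 and mass in grams.
#'
#' The window defining the flux is configurable because the early part of
#' a drying curve still contains stomatal water loss:
#' \describe{
#'   \item{`"last60"`}{(default) the final 60 minutes, when stomata are
#'     assumed fully closed;}
#'   \item{`"full"`}{the whole series;}
#'   \item{`"best"`}{the contiguous window of >= 6 points with maximum
#'     linear R2 (ties broken toward the longest, then latest, window).}
#' }
#'
#' @param series A [mass_loss_series()].
#' @param window One of `"last60"`, `"full"`, `"best"`.
#' @return A list with `E_MLD` (mol m-2 s-1), `se` (its standard error),
#'   `window` (start/end seconds actually used), `n` points used, and
#'   `quality` (`"ok"` or `"negative-rate"` for a mass-gaining series;
#'   the value is reported as-is, not clamped).
#' @export
estimate_mass_loss_rate <- function(series, window = c("last60", "full", "best")) {
  stopifnot(inherits(series, "mass_loss_series"))
  window <- match.arg(window)
  t <- series$times
  m <- series$masses
  idx <- switch(window,
    full = seq_along(t),
    last60 = which(t >= max(t) - 3600),
    best = best_linear_window(t, m)
  )
  if (length(idx) < 3) {
    stop("estimate_mass_loss_rate: fewer than 3 points in the selected window",
         call. = FALSE)
  }
  fit <- stats::lm(m[idx] ~ t[idx])
  slope <- unname(stats::coef(fit)[2])
  # closed-form slope SE (stays quiet on exactly collinear series)
  rss <- sum(stats::resid(fit)^2)
  sxx <- sum((t[idx] - mean(t[idx]))^2)
  se_slope <- sqrt(rss / (length(idx) - 2) / sxx)
  denom <- MOLAR_MASS_WATER * series$area
  E <- -slope / denom
  quality <- "ok"
  if (E < 0) {
    warning("estimate_mass_loss_rate: mass increases over the window; ",
            "negative flux reported with quality flag", call. = FALSE)
    quality <- "negative-rate"
  }
  list(E_MLD = E, se = se_slope / denom,
       window = c(start = min(t[idx]), end = max(t[idx])),
       n = length(idx), quality = quality)
}

# maximum-R2 contiguous window of >= 6 points (or all points if fewer)
best_linear_window <- function(t, m) {
  n <- length(t)
  minlen <- min(6L, n)
  best <- seq_len(n)
  best_r2 <- -Inf
  for (len in minlen:n) {
    for (start in 1:(n - len + 1)) {
      idx <- start:(start + len - 1L)
      r2 <- stats::cor(t[idx], m[idx])^2
      if (is.na(r2)) r2 <- 0
      # prefer higher R2, then longer, then later windows
      if (r2 > best_r2 + 1e-12) {
        best_r2 <- r2
        best <- idx
      }
    }
  }
  best
}

#' Residual conductance from a water-loss flux
#'
#' \eqn{g_{MLD} = E_{MLD} \, P / D}, expressed in mmol m-2 s-1. Linear in
#' the flux; halves when the vapor pressure deficit doubles.
#'
#' @param E_MLD Water-loss flux (mol m-2 s-1).
#' @param air An [air_state()]; its vapor pressure deficit must be > 0
#'   (saturated air makes the conductance undefined).
#' @return Residual conductance (mmol m-2 s-1).
#' @examples
#' gmld_from_rate(1.10e-4, air_state(25, 0.30, 101.3))
#' @export
gmld_from_rate <- function(E_MLD, air) {
  stopifnot(is.numeric(E_MLD), inherits(air, "air_state"))
  D <- vapor_pressure_deficit(air)
  if (any(D <= 0)) {
    stop("gmld_from_rate: D = 0 (saturated air) leaves conductance undefined",
         call. = FALSE)
  }
  mol_to_mmol(E_MLD * air$P_atm / D)
}

#' Full mass-loss pipeline for one leaf
#'
#' Convenience composition of [estimate_mass_loss_rate()] and
#' [gmld_from_rate()].
#'
#' @inheritParams estimate_mass_loss_rate
#' @return Residual conductance estimate as a one-row data.frame with
#'   columns `gmld_mmol`, `se_mmol`, `window_start`, `window_end`, `n`,
#'   `quality`.
#' @export
gmld_from_series <- function(series, window = c("last60", "full", "best")) {
  rate <- estimate_mass_loss_rate(series, window)
  D <- vapor_pressure_deficit(series$air)
  scale <- series$air$P_atm / D
  data.frame(
    gmld_mmol = mol_to_mmol(rate$E_MLD * scale),
    se_mmol = mol_to_mmol(rate$se * scale),
    window_start = rate$window[["start"]],
    window_end = rate$window[["end"]],
    n = rate$n,
    quality = rate$quality
  )
}

#' Residual-conductance estimates from gas-exchange records
#'
#' The two instrument-based routes to residual conductance: nocturnal
#' conductance (`"nocturnal"`: night-period records, where a high
#' chamber vapor pressure deficit is assumed to have forced stomatal
#' closure) and daytime conductance (`"daytime"`: day-period records
#' kept only where net assimilation is at or below `A_threshold`
#' umol m-2 s-1, the screen under which daytime conductance approximates
#' a residual rather than an active stomatal flux).
#'
#' @param records Gas-exchange records with columns `gs_mol`, `A_umol`,
#'   `period`, `species`, `light`, `water`.
#' @param method `"nocturnal"` or `"daytime"`.
#' @param A_threshold Assimilation screen for the daytime route
#'   (umol m-2 s-1), default 1.
#' @return data.frame of estimates (`value` in mmol m-2 s-1, `method`,
#'   `species`, `light`, `water`) for [assign_g0_gmin()].
#' @export
residual_estimates_from_records <- function(records,
                                            method = c("nocturnal",
                                                       "daytime"),
                                            A_threshold = 1) {
  method <- match.arg(method)
  keep <- if (method == "nocturnal") {
    records$period == "night"
  } else {
    records$period == "day" & records$A_umol <= A_threshold
  }
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0) {
    stop("residual_estimates_from_records: no records pass the '",
         method, "' screen", call. = FALSE)
  }
  data.frame(value = mol_to_mmol(r$gs_mol), method = method,
             species = r$species, light = r$light, water = r$water)
}

#' Treatment-level g0 and gmin from residual-conductance estimates
#'
#' The intercept-like floor candidates of the minimum-conductance stomatal
#' models are defined from the treatment factorial: `g0` is mean residual
#' conductance in the deep-shade, well-watered cell (P0 x shade) and
#' `gmin` the mean in the full-sun, strong-drought cell (P80 x sun).
#' Per-leaf estimates are computed first and then averaged within a cell.
#'
#' @param estimates data.frame with columns `value` (mmol m-2 s-1),
#'   `method` (one of `"MLD"`, `"nocturnal"`, `"daytime"`), `species`,
#'   `light` (`"sun"`/`"shade"`), `water` (`"P0"`/`"P50"`/`"P80"`).
#' @param method Which measurement route to aggregate.
#' @param species Optional species filter; default aggregates every
#'   species present.
#' @return data.frame with one row per species: `species`, `g0_mmol`,
#'   `gmin_mmol`, `n_g0`, `n_gmin`.
#' @export
assign_g0_gmin <- function(estimates, method = c("MLD", "nocturnal", "daytime"),
                           species = NULL) {
  method <- match.arg(method)
  need <- c("value", "method", "species", "light", "water")
  if (!all(need %in% names(estimates))) {
    stop("assign_g0_gmin: estimates must have columns ",
         paste(setdiff(need, names(estimates)), collapse = ", "),
         call. = FALSE)
  }
  est <- estimates[estimates$method == method, , drop = FALSE]
  if (!is.null(species)) est <- est[est$species %in% species, , drop = FALSE]
  if (nrow(est) == 0) {
    stop("assign_g0_gmin: no estimates for method '", method, "'",
         call. = FALSE)
  }
  if (any(est$value < 0)) {
    stop("assign_g0_gmin: negative residual-conductance estimate",
         call. = FALSE)
  }
  sp <- unique(est$species)
  out <- lapply(sp, function(s) {
    e <- est[est$species == s, , drop = FALSE]
    g0_cell <- e$value[e$water == "P0" & e$light == "shade"]
    gmin_cell <- e$value[e$water == "P80" & e$light == "sun"]
    if (length(g0_cell) == 0) {
      stop("assign_g0_gmin: no P0 x shade estimates for species '", s,
           "' with method '", method, "'", call. = FALSE)
    }
    if (length(gmin_cell) == 0) {
      stop("assign_g0_gmin: no P80 x sun estimates for species '", s,
           "' with method '", method, "'", call. = FALSE)
    }
    data.frame(species = s, g0_mmol = mean(g0_cell),
               gmin_mmol = mean(gmin_cell),
               n_g0 = length(g0_cell), n_gmin = length(gmin_cell))
  })
  do.call(rbind, out)
}
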