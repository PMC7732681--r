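#' Farquhar-von Caemmerer-Berry parameter set
#'
#' Kinetic parameters of the biochemical photosynthesis model, referenced
#' to 25 degrees C and adjusted to leaf temperature with Arrhenius
#' responses. Defaults for the Rubisco constants and activation energies
#' follow the widely used in-vivo tobacco calibration (Bernacchi and
#' colleagues); the quantum yield `alpha` and curvature `theta` take
#' common broadleaf values. All are overridable.
#'
#' @param Vcmax25 Maximum carboxylation rate at 25 C (umol m-2 s-1).
#' @param Jmax25 Maximum electron transport rate at 25 C (umol m-2 s-1).
#' @param Rd25 Day respiration at 25 C (umol m-2 s-1).
#' @param Gamma_star25 CO2 compensation point without Rd at 25 C
#'   (umol mol-1).
#' @param Kc25 Michaelis constant for CO2 at 25 C (umol mol-1).
#' @param Ko25 Michaelis constant for O2 at 25 C (mmol mol-1).
#' @param O Oxygen mole fraction (mmol mol-1).
#' @param theta Curvature of the light response of J, in (0, 1].
#' @param alpha Quantum yield of electron transport (mol e- / mol photon),
#'   in (0, 0.5).
#' @param Ea Named list of activation energies (J mol-1) for `Vcmax`,
#'   `Jmax`, `Rd`, `Gamma_star`, `Kc`, `Ko`.
#' @param Hd Deactivation energy (J mol-1) of the peaked temperature
#'   response applied to Vcmax and Jmax; with `dS` it places the thermal
#'   optimum near 38 C so capacity declines under heat instead of rising
#'   without bound.
#' @param dS Entropy term (J mol-1 K-1) of the peaked response.
#' @return An object of class `fvcb_params`.
#' @export
fvcb_params <- function(Vcmax25 = 60, Jmax25 = 120, Rd25 = 1,
                        Gamma_star25 = 42.75, Kc25 = 404.9, Ko25 = 278.4,
                        O = 210, theta = 0.9, alpha = 0.3,
                        Ea = list(Vcmax = 65330, Jmax = 43540, Rd = 46390,
                                  Gamma_star = 37830, Kc = 79430,
                                  Ko = 36380),
                        Hd = 200000, dS = 650) {
  rates <- c(Vcmax25 = Vcmax25, Jmax25 = Jmax25, Rd25 = Rd25,
             Gamma_star25 = Gamma_star25, Kc25 = Kc25, Ko25 = Ko25, O = O)
  if (any(rates <= 0)) {
    stop("fvcb_params: all rates and concentrations must be > 0",
         call. = FALSE)
  }
  if (theta <= 0 || theta > 1) {
    stop("fvcb_params: theta must lie in (0, 1]", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 0.5) {
    stop("fvcb_params: alpha must lie in (0, 0.5)", call. = FALSE)
  }
  structure(list(Vcmax25 = Vcmax25, Jmax25 = Jmax25, Rd25 = Rd25,
                 Gamma_star25 = Gamma_star25, Kc25 = Kc25, Ko25 = Ko25,
                 O = O, theta = theta, alpha = alpha, Ea = Ea,
                 Hd = Hd, dS = dS),
            class = "fvcb_params")
}

# Arrhenius temperature adjustment from 25 C reference
arrhenius <- function(k25, Ea, T_leaf) {
  R <- 8.314
  Tk <- T_leaf + 273.15
  k25 * exp(Ea * (Tk - 298.15) / (298.15 * R * Tk))
}

# peaked (deactivating) Arrhenius for the capacity parameters
peaked_arrhenius <- function(k25, Ea, T_leaf, Hd, dS) {
  R <- 8.314
  Tk <- T_leaf + 273.15
  arrhenius(k25, Ea, T_leaf) *
    (1 + exp((298.15 * dS - Hd) / (298.15 * R))) /
    (1 + exp((Tk * dS - Hd) / (Tk * R)))
}

# all temperature-adjusted kinetic quantities at leaf temperature
fvcb_at_T <- function(params, T_leaf) {
  list(
    Vcmax = peaked_arrhenius(params$Vcmax25, params$Ea$Vcmax, T_leaf,
                             params$Hd, params$dS),
    Jmax = peaked_arrhenius(params$Jmax25, params$Ea$Jmax, T_leaf,
                            params$Hd, params$dS),
    Rd = arrhenius(params$Rd25, params$Ea$Rd, T_leaf),
    Gamma_star = arrhenius(params$Gamma_star25, params$Ea$Gamma_star, T_leaf),
    Kc = arrhenius(params$Kc25, params$Ea$Kc, T_leaf),
    Ko = arrhenius(params$Ko25, params$Ea$Ko, T_leaf)
  )
}

# smaller root of theta J^2 - (alpha PAR + Jmax) J + alpha PAR Jmax = 0
electron_transport <- function(PAR, Jmax, theta, alpha) {
  b <- alpha * PAR + Jmax
  (b - sqrt(b^2 - 4 * theta * alpha * PAR * Jmax)) / (2 * theta)
}

#' Net assimilation from the FvCB model
#'
#' \eqn{A = \min(A_c, A_j) - R_d} with the Rubisco-limited rate
#' \eqn{A_c = V_{cmax}(C_i - \Gamma^*) / (C_i + K_c(1 + O/K_o))} and the
#' electron-transport-limited rate
#' \eqn{A_j = J (C_i - \Gamma^*) / (4 C_i + 8 \Gamma^*)}, where J is the
#' smaller root of the non-rectangular hyperbola in PAR. No triose
#' phosphate limitation and no mesophyll conductance: `Ci` is the
#' substrate concentration.
#'
#' @param Ci Intercellular CO2 (umol mol-1), >= 0; vectorized.
#' @param PAR Photosynthetic photon flux density (umol m-2 s-1).
#' @param T_leaf Leaf temperature (degrees C).
#' @param params An [fvcb_params()].
#' @return Net assimilation (umol m-2 s-1).
#' @export
fvcb_assimilation <- function(Ci, PAR, T_leaf, params) {
  stopifnot(inherits(params, "fvcb_params"))
  if (any(Ci < 0)) stop("fvcb_assimilation: Ci must be >= 0", call. = FALSE)
  if (any(PAR < 0)) stop("fvcb_assimilation: PAR must be >= 0", call. = FALSE)
  k <- fvcb_at_T(params, T_leaf)
  Ac <- k$Vcmax * (Ci - k$Gamma_star) / (Ci + k$Kc * (1 + params$O / k$Ko))
  J <- electron_transport(PAR, k$Jmax, params$theta, params$alpha)
  Aj <- J * (Ci - k$Gamma_star) / (4 * Ci + 8 * k$Gamma_star)
  pmin(Ac, Aj) - k$Rd
}

#' Fit Vcmax, Jmax and Rd to an A/Ci curve
#'
#' Nonlinear least squares of observed assimilation on the FvCB
#' prediction under the min-rule, with the Rubisco kinetic constants
#' (`Gamma_star`, `Kc`, `Ko`) held fixed at their temperature-adjusted
#' values. Starting values come from a closed-form Rubisco-limited fit of
#' the low-Ci points and an electron-transport fit of the high-Ci
#' points; Levenberg-Marquardt refinement, with a Nelder-Mead fallback at
#' the non-smooth transition.
#'
#' @param curve data.frame with columns `Ci_umol`, `A_umol` and (scalar
#'   or per-point) `PAR_umol`, `T_C`; >= 6 points spanning sub- and
#'   supra-ambient Ci. Measured at saturating light.
#' @param params Template [fvcb_params()] supplying the fixed kinetics,
#'   `theta` and `alpha`.
#' @return A list: `params` (an [fvcb_params()] with fitted `Vcmax25`,
#'   `Jmax25`, `Rd25`), `RSS`, `fitted` values, and `ill_determined`
#'   (TRUE when the curve never leaves one limitation regime, e.g. all
#'   Ci > 600 leaves Vcmax unconstrained).
#' @export
fit_aci <- function(curve, params = fvcb_params()) {
  need <- c("Ci_umol", "A_umol", "PAR_umol", "T_C")
  if (!all(need %in% names(curve))) {
    stop("fit_aci: curve must have columns ",
         paste(setdiff(need, names(curve)), collapse = ", "), call. = FALSE)
  }
  if (nrow(curve) < 6) stop("fit_aci: need >= 6 points", call. = FALSE)
  Ci <- curve$Ci_umol
  A <- curve$A_umol
  PAR <- curve$PAR_umol
  T_leaf <- curve$T_C[1]
  k <- fvcb_at_T(params, T_leaf)

  low <- Ci < 350
  high <- Ci > 450
  ill <- sum(low) < 2 || sum(high) < 2
  if (ill) {
    warning("fit_aci: curve does not span both limitation regimes; ",
            "estimates may be ill-determined", call. = FALSE)
  }

  # Rubisco-limited start from low-Ci points: A = Vcmax*f(Ci) - Rd
  f_c <- (Ci - k$Gamma_star) / (Ci + k$Kc * (1 + params$O / k$Ko))
  idx <- if (sum(low) >= 2) low else seq_along(Ci)
  st <- stats::coef(stats::lm(A[idx] ~ f_c[idx]))
  Vc_start <- max(unname(st[2]), 5)
  Rd_start <- max(-unname(st[1]), 0.1)
  # J start from high-Ci points, then invert the light response for Jmax
  f_j <- (Ci - k$Gamma_star) / (4 * Ci + 8 * k$Gamma_star)
  idx <- if (sum(high) >= 2) high else seq_along(Ci)
  J_start <- max(stats::median((A[idx] + Rd_start) / f_j[idx]), 5)
  Jmax_start <- max(J_start * 1.2, Vc_start)

  # rescale 25 C reference so the temperature-adjusted values hit the starts
  to25 <- function(kT, which) kT / arrhenius(1, params$Ea[[which]], T_leaf)
  model_rss <- function(p) {
    pr <- params
    pr$Vcmax25 <- p[1]; pr$Jmax25 <- p[2]; pr$Rd25 <- p[3]
    sum((A - fvcb_assimilation(Ci, PAR, T_leaf, pr))^2)
  }
  start <- c(to25(Vc_start, "Vcmax"), to25(Jmax_start, "Jmax"),
             to25(Rd_start, "Rd"))

  fit <- tryCatch({
    nls_fit <- minpack.lm::nlsLM(
      A ~ {
        pr <- params
        pr$Vcmax25 <- Vcmax25; pr$Jmax25 <- Jmax25; pr$Rd25 <- Rd25
        fvcb_assimilation(Ci, PAR, T_leaf, pr)
      },
      start = list(Vcmax25 = start[1], Jmax25 = start[2], Rd25 = start[3]),
      lower = c(1, 1, 0.01), upper = c(500, 1000, 20),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    unname(stats::coef(nls_fit))
  }, error = function(e) NULL)
  # polish (or replace, if Levenberg-Marquardt failed at the kink)
  opt <- stats::optim(fit %||% start, model_rss, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- opt$par

  out <- params
  out$Vcmax25 <- p[1]; out$Jmax25 <- p[2]; out$Rd25 <- p[3]
  list(params = out, RSS = model_rss(p),
       fitted = fvcb_assimilation(Ci, PAR, T_leaf, out),
       ill_determined = ill)
}

#' Solve the coupled assimilation-conductance-diffusion system
#'
#' Finds the intercellular CO2 at which biochemical demand equals
#' diffusive supply, \eqn{A(C_i) = (g_s / 1.6)(C_a - C_i)}, with the
#' stomatal model evaluated self-consistently at the current candidate
#' (\eqn{g_s = g_s(A(C_i))}; 1.6 is the water-to-CO2 diffusivity ratio
#' and boundary-layer conductance is infinite). Solved by bisection on
#' `Ci` over \[1, 3 Ca\]; when a respiring leaf with a very small
#' conductance floor pushes the balance point above that range, the
#' upper bracket is expanded once to 50 Ca before giving up. The returned
#' residual is below 1e-6 umol m-2 s-1.
#'
#' @param spec A fitted [stomatal_spec()].
#' @param params An [fvcb_params()].
#' @param env Named list or vector with `PAR` (umol m-2 s-1), `T` (C),
#'   `Ca` (umol mol-1), `RH` (fraction) and optionally `P` (kPa, default
#'   101.325).
#' @return A list of class `coupled_state`: `A` (umol m-2 s-1), `gs`
#'   (mol m-2 s-1), `Ci` (umol mol-1), `E_l` (mmol m-2 s-1), `residual`,
#'   and the environment.
#' @export
solve_coupled <- function(spec, params, env) {
  stopifnot(inherits(spec, "stomatal_spec"), inherits(params, "fvcb_params"))
  env <- as.list(env)
  if (is.null(env[["P"]])) env[["P"]] <- 101.325
  Ca <- env$Ca
  # during bracketing an additive BB form can predict gs <= 0 at probe
  # points far from the solution (strongly negative A); clamp there and
  # reject only a non-physical *solution*
  resid <- function(Ci) {
    A <- fvcb_assimilation(Ci, env$PAR, env$T, params)
    gs <- max(predict_gs(spec, A, env$RH, Ca), 1e-9)
    A - (gs / 1.6) * (Ca - Ci)
  }
  lo <- 1
  hi <- 3 * Ca
  flo <- resid(lo)
  fhi <- resid(hi)
  if (flo * fhi > 0) {
    hi <- 50 * Ca
    fhi <- resid(hi)
    if (flo * fhi > 0) {
      stop("solve_coupled: no sign change on Ci in [1, ", hi,
           "]; residuals ", signif(flo, 4), " and ", signif(fhi, 4),
           call. = FALSE)
    }
  }
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    fm <- resid(mid)
    if (abs(fm) < 1e-9 || (hi - lo) < 1e-10) break
    if (flo * fm <= 0) {
      hi <- mid
    } else {
      lo <- mid
      flo <- fm
    }
  }
  Ci <- mid
  A <- fvcb_assimilation(Ci, env$PAR, env$T, params)
  gs <- predict_gs(spec, A, env$RH, Ca)
  if (gs <= 0) {
    stop("solve_coupled: non-physical gs <= 0 at the solution (A = ",
         signif(A, 4), "); check the stomatal spec", call. = FALSE)
  }
  D <- vapor_pressure_deficit(air_state(env$T, env$RH, env$P))
  structure(list(A = A, gs = gs, Ci = Ci,
                 E_l = transpiration_rate(gs, D, env$P),
                 residual = fm, env = env),
            class = "coupled_state")
}

#' Sweep the coupled model over a light or temperature gradient
#'
#' Runs [solve_coupled()] for each spec at each grid point and returns a
#' tidy table — the numerical experiment behind "what does the choice of
#' residual-conductance floor do to intercellular CO2 and transpiration".
#' A spec differing only by a larger floor yields pointwise larger Ci
#' across a light gradient and larger E_l across a temperature gradient.
#'
#' @param specs Named list of [stomatal_spec()] objects.
#' @param params An [fvcb_params()].
#' @param sweep `"par"` or `"temp"`.
#' @param grid Numeric grid of PAR (umol m-2 s-1) or temperature (C).
#' @param env Base environment (list with `T`, `Ca`, `RH`, `P`; `PAR` for
#'   a temperature sweep). Relative humidity is held fixed, so the vapor
#'   pressure deficit rises with temperature along a temperature sweep.
#' @return data.frame: `spec`, `PAR`, `T`, `A`, `gs`, `Ci`, `E_l`,
#'   `error` (NA, or the solver message for grid points with no
#'   admissible solution).
#' @export
simulate_response <- function(specs, params, sweep = c("par", "temp"),
                              grid = NULL,
                              env = list(T = 25, Ca = 400, RH = 0.5,
                                         P = 101.325, PAR = 1500)) {
  sweep <- match.arg(sweep)
  if (is.null(grid)) {
    grid <- if (sweep == "par") seq(0, 1500, by = 50) else seq(10, 45, by = 1)
  }
  if (length(grid) == 0) stop("simulate_response: empty grid", call. = FALSE)
  if (is.null(names(specs))) names(specs) <- paste0("spec", seq_along(specs))
  rows <- list()
  for (nm in names(specs)) {
    for (g in grid) {
      e <- env
      if (sweep == "par") e$PAR <- g else e$T <- g
      st <- tryCatch(solve_coupled(specs[[nm]], params, e),
                     error = function(err) err)
      if (inherits(st, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          spec = nm, PAR = e$PAR, T = e$T, A = NA_real_, gs = NA_real_,
          Ci = NA_real_, E_l = NA_real_, error = conditionMessage(st))
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          spec = nm, PAR = e$PAR, T = e$T, A = st$A, gs = st$gs,
          Ci = st$Ci, E_l = st$E_l, error = NA_character_)
      }
    }
  }
  do.call(rbind, rows)
}
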