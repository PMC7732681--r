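#' Synthetic factorial design
#'
#' Ground-truth description of the simulated experiment that every other
#' module is tested against: two species grown under two light levels
#' (sun, PAR 1500; shade, PAR 40 umol m-2 s-1) crossed with three water
#' treatments (P0 none, P50 substantial, P80 severe loss of hydraulic
#' conductivity), measured both under growth light and with the light
#' levels swapped. Water stress scales photosynthetic capacity; each
#' species carries a true stomatal model and true FvCB parameters; the
#' residual-conductance cell means default to values typical of
#' Mediterranean oaks (a few mmol m-2 s-1, declining with drought in the
#' sun and lowest in well-watered shade).
#'
#' @param species Character vector of species labels.
#' @param replicates Leaves per treatment cell (>= 1).
#' @param gs_noise_sd Gaussian noise sd on observed gs (mol m-2 s-1).
#' @param mass_noise_sd Weighing noise sd (g); default 0.5 mg.
#' @param aci_noise_sd Noise sd on assimilation in A/Ci curves
#'   (umol m-2 s-1).
#' @param true_specs Named list (by species) of true [stomatal_spec()]s.
#' @param true_params Named list (by species) of true [fvcb_params()].
#' @param gres_cells data.frame of true residual-conductance cell means
#'   (mmol m-2 s-1) with columns `light`, `water`, `gres_mmol`.
#' @param water_capacity_scale Named numeric: multiplier on Vcmax/Jmax
#'   per water treatment.
#' @param Ca Chamber CO2 (umol mol-1). @param RH Chamber relative
#'   humidity target (fraction). @param T_day Chamber block temperature
#'   (C) for daytime records.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(
    species = c("species_A", "species_B"),
    replicates = 5,
    gs_noise_sd = 0.005,
    mass_noise_sd = 5e-4,
    aci_noise_sd = 0.5,
    true_specs = NULL,
    true_params = NULL,
    gres_cells = data.frame(
      light = rep(c("sun", "shade"), each = 3),
      water = rep(c("P0", "P50", "P80"), 2),
      gres_mmol = c(7.4, 6.2, 5.5, 4.0, 3.1, 5.0)),
    water_capacity_scale = c(P0 = 1, P50 = 0.55, P80 = 0.25),
    Ca = 400, RH = 0.30, T_day = 30) {
  if (replicates < 1) {
    stop("synthetic_design: replicates must be >= 1", call. = FALSE)
  }
  if (gs_noise_sd < 0 || mass_noise_sd < 0 || aci_noise_sd < 0) {
    stop("synthetic_design: noise sds must be >= 0", call. = FALSE)
  }
  if (is.null(true_specs)) {
    true_specs <- stats::setNames(lapply(species, function(s)
      stomatal_spec("BBD", m = 9, g0 = 0.0055, gmin = 0.0055,
                    floor_source = "MLD")), species)
  }
  if (is.null(true_params)) {
    true_params <- stats::setNames(
      lapply(species, function(s) fvcb_params()), species)
  }
  structure(list(species = species, replicates = replicates,
                 gs_noise_sd = gs_noise_sd, mass_noise_sd = mass_noise_sd,
                 aci_noise_sd = aci_noise_sd,
                 true_specs = true_specs, true_params = true_params,
                 gres_cells = gres_cells,
                 water_capacity_scale = water_capacity_scale,
                 Ca = Ca, RH = RH, T_day = T_day),
            class = "synthetic_design")
}

# capacity-scaled copy of a species' FvCB parameters for a water level
scale_capacity <- function(params, factor) {
  params$Vcmax25 <- params$Vcmax25 * factor
  params$Jmax25 <- params$Jmax25 * factor
  params
}

#' Generate factorial gas-exchange records with known truth
#'
#' For every species x light x water cell and replicate, draws a chamber
#' environment (CO2 400 umol mol-1, relative humidity jittered around the
#' 30% set point), computes assimilation from the true coupled
#' leaf model (water stress scaling photosynthetic capacity), takes the
#' true stomatal model's conductance and adds Gaussian observation noise.
#' Records are emitted for both measurement roles: `growth` (sun leaves
#' at PAR 1500, shade leaves at 40 — the calibration set) and `swapped`
#' (light levels exchanged — the validation set).
#'
#' @param design A [synthetic_design()].
#' @param seed Integer seed; same seed, identical table.
#' @param roles Which measurement roles to emit (default both).
#' @return data.frame of records (`species`, `light`, `water`, `period`,
#'   `role`, `PAR_umol`, `A_umol`, `gs_mol`, `gs_true_mol`, `Ca_umol`,
#'   `RH_frac`, `D_kPa`, `T_C`), with the generating design attached as
#'   attribute `ground_truth`.
#' @export
gen_gas_exchange <- function(design, seed = 1,
                             roles = c("growth", "swapped")) {
  roles <- match.arg(roles, several.ok = TRUE)
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(seed)
  rows <- list()
  for (sp in design$species) {
    spec <- design$true_specs[[sp]]
    base_params <- design$true_params[[sp]]
    for (light in c("sun", "shade")) {
      for (water in c("P0", "P50", "P80")) {
        params <- scale_capacity(base_params,
                                 design$water_capacity_scale[[water]])
        for (role in roles) {
          PAR <- if ((light == "sun") == (role == "growth")) 1500 else 40
          for (rep in seq_len(design$replicates)) {
            RH <- min(0.95, max(0.05, stats::rnorm(1, design$RH, 0.02)))
            env <- list(PAR = PAR, T = design$T_day, Ca = design$Ca, RH = RH)
            st <- solve_coupled(spec, params, env)
            gs_obs <- st$gs + stats::rnorm(1, 0, design$gs_noise_sd)
            rows[[length(rows) + 1]] <- data.frame(
              species = sp, light = light, water = water, period = "day",
              role = role, PAR_umol = PAR, A_umol = st$A,
              gs_mol = gs_obs, gs_true_mol = st$gs,
              Ca_umol = design$Ca, RH_frac = RH,
              D_kPa = vapor_pressure_deficit(
                air_state(design$T_day, RH)),
              T_C = design$T_day)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ground_truth") <- design
  out
}

#' Generate a detached-leaf drying curve with known residual conductance
#'
#' Constant-deficit drying: mass declines linearly at the rate implied by
#' the residual conductance, \eqn{dm/dt = -(g/1000)(D/P) \cdot area
#' \cdot M_w} grams per second, plus Gaussian weighing noise. Defaults
#' reproduce a 2-h protocol of 5-min weighings (25 points).
#'
#' @param g_res_true True residual conductance (mmol m-2 s-1), >= 0.
#' @param area Projected leaf area (m2).
#' @param air An [air_state()] for the drying lab.
#' @param interval Weighing interval (s). @param duration Total drying
#'   time (s); must cover >= 3 intervals.
#' @param noise_sd Weighing noise sd (g). @param seed Integer seed.
#' @param m0 Initial leaf fresh mass (g).
#' @return A [mass_loss_series()] with attribute `g_res_true`.
#' @export
gen_mass_loss_series <- function(g_res_true, area = 1e-3,
                                 air = air_state(25, 0.30, 101.325),
                                 interval = 300, duration = 7200,
                                 noise_sd = 5e-4, seed = 1, m0 = 0.5) {
  if (g_res_true < 0) {
    stop("gen_mass_loss_series: g_res_true must be >= 0", call. = FALSE)
  }
  if (duration < 3 * interval) {
    stop("gen_mass_loss_series: duration must cover >= 3 intervals",
         call. = FALSE)
  }
  set.seed(seed)
  times <- seq(0, duration, by = interval)
  D <- vapor_pressure_deficit(air)
  rate_g_per_s <- mmol_to_mol(g_res_true) * (D / air$P_atm) * area *
    MOLAR_MASS_WATER
  masses <- m0 - rate_g_per_s * times +
    stats::rnorm(length(times), 0, noise_sd)
  out <- mass_loss_series(times, masses, area, air)
  attr(out, "g_res_true") <- g_res_true
  out
}

# standard stepped-CO2 measurement sequence (umol mol-1); the nominal
# 0-ppm step is run at 5 to keep the diffusion relation finite
ACI_CA_SEQUENCE <- c(400, 300, 250, 200, 150, 100, 50, 5,
                     400, 500, 650, 800, 1000, 1250, 1500)

#' Generate an A/Ci response curve with known FvCB truth
#'
#' Walks the stepped ambient-CO2 sequence at saturating light, solving
#' the coupled leaf model with a plausible floored stomatal spec at each
#' set point to obtain a consistent (Ci, A) pair, then adds Gaussian
#' noise to A. The nominal 0-ppm step is emitted at Ca = 5 umol mol-1
#' (flagged in `Ca_set_umol`) so the diffusion relation stays finite.
#'
#' @param params True [fvcb_params()].
#' @param noise_sd Noise sd on A (umol m-2 s-1). @param seed Integer
#'   seed.
#' @param T_leaf Leaf temperature (C). @param PAR Light level
#'   (umol m-2 s-1), saturating by default.
#' @param spec Stomatal spec used to close the gas-exchange loop at each
#'   set point.
#' @return data.frame (`Ca_set_umol`, `Ci_umol`, `A_umol`, `PAR_umol`,
#'   `T_C`) with attribute `params_true`.
#' @export
gen_aci_curve <- function(params, noise_sd = 0.5, seed = 1,
                          T_leaf = 30, PAR = 1500,
                          spec = stomatal_spec("BBD", m = 9, g0 = 0.01,
                                               gmin = 0.01)) {
  stopifnot(inherits(params, "fvcb_params"))
  set.seed(seed)
  rows <- lapply(ACI_CA_SEQUENCE, function(Ca) {
    st <- solve_coupled(spec, params,
                        list(PAR = PAR, T = T_leaf, Ca = Ca, RH = 0.5))
    data.frame(Ca_set_umol = Ca, Ci_umol = st$Ci,
               A_umol = st$A + stats::rnorm(1, 0, noise_sd),
               PAR_umol = PAR, T_C = T_leaf)
  })
  out <- do.call(rbind, rows)
  attr(out, "params_true") <- params
  out
}

#' Generate per-leaf residual-conductance estimates around cell means
#'
#' Draws replicate leaf-level estimates for every species x light x
#' water cell of the design, Gaussian around the design's true cell
#' means, and returns them in the shape [assign_g0_gmin()] consumes.
#'
#' @param design A [synthetic_design()].
#' @param method Measurement-route tag for the emitted estimates.
#' @param sd Between-leaf sd (mmol m-2 s-1).
#' @param seed Integer seed.
#' @return data.frame with columns `value`, `method`, `species`, `light`,
#'   `water`.
#' @export
gen_gres_estimates <- function(design, method = "MLD", sd = 0.8, seed = 1) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(seed)
  cells <- design$gres_cells
  rows <- list()
  for (sp in design$species) {
    for (i in seq_len(nrow(cells))) {
      vals <- pmax(0, stats::rnorm(design$replicates, cells$gres_mmol[i], sd))
      rows[[length(rows) + 1]] <- data.frame(
        value = vals, method = method, species = sp,
        light = cells$light[i], water = cells$water[i])
    }
  }
  do.call(rbind, rows)
}
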