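# shared fixtures, built in code

default_air <- function() air_state(25, 0.30, 101.325)

# exact Ball-Berry records (no noise) from a known spec
make_bb_records <- function(spec, A, RH = 0.3, Ca = 400) {
  gs <- predict_gs(spec, A, RH, Ca)
  data.frame(A_umol = A, gs_mol = gs, Ca_umol = Ca, RH_frac = RH)
}

# one-species factorial design with a BBD truth, sized for ~n calibration
# records (2 light x 3 water cells per role)
bbd_design <- function(replicates = 34, m = 9, floor = 0.0055) {
  synthetic_design(
    species = "sp",
    replicates = replicates,
    true_specs = list(sp = stomatal_spec("BBD", m = m, g0 = floor,
                                         gmin = floor,
                                         floor_source = "MLD")))
}

bb_design <- function(replicates = 34, m = 9, gint = 0.0089) {
  synthetic_design(
    species = "sp",
    replicates = replicates,
    true_specs = list(sp = stomatal_spec("BB", m = m, gint = gint)))
}

# brute-force oracle for the coupled solver: scan Ci on a fixed-step grid
# and return the grid point with the smallest |demand - supply| residual
grid_scan_ci <- function(spec, params, env, step = 0.01, upper = NULL) {
  Ca <- env$Ca
  if (is.null(upper)) upper <- 3 * Ca
  Ci <- seq(1, upper, by = step)
  A <- fvcb_assimilation(Ci, env$PAR, env$T, params)
  gs <- pmax(predict_gs(spec, A, env$RH, Ca), 1e-9)
  resid <- A - (gs / 1.6) * (Ca - Ci)
  Ci[which.min(abs(resid))]
}
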