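---
title: "Residual leaf conductance in stomatal models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual leaf conductance in stomatal models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomres)
```

## The problem

When stomata close — at night, in deep shade, or under severe drought —
leaves keep losing water through the cuticle and through imperfectly
sealed stomata. This *residual conductance* (g_res, a few
mmol m⁻² s⁻¹) is small next to midday stomatal conductance but matters
disproportionately: it sets the floor of every stomatal model, controls
simulated water loss during drought, and is measured by at least three
non-equivalent routes. `stomres` implements the full chain: estimating
g_res from each route, embedding the estimates in the Ball–Berry model
family, comparing those models by AIC, and propagating the choice of
floor through a coupled photosynthesis–conductance simulation.

## Measurement routes for g_res

* **Drying curves (g_MLD).** A detached leaf with a sealed petiole is
  weighed repeatedly (default protocol: every 300 s for 7200 s, 25
  weighings). The ordinary least-squares slope of mass on time, divided
  by the molar mass of water (18.015 g mol⁻¹) and projected leaf area,
  gives the water-loss flux E (mol m⁻² s⁻¹), and

  g_MLD = E · P / D (mmol m⁻² s⁻¹ after rescaling),

  with P the air pressure and D the vapor pressure deficit of the lab
  air, both taken constant over the drying period. Because the early
  part of the curve still contains stomatal water loss, the flux window
  is configurable: the final 60 min (default, stomata assumed closed),
  the full series, or the maximum-R² contiguous window of ≥ 6 points.
  Whichever is chosen is reported with the estimate. Per-leaf estimates
  are computed first and then averaged within treatment cells; the
  alternative (pooling masses before inversion) differs only through
  the weighting of leaves and is not implemented.

* **Nocturnal conductance (g_n).** Night-period gas-exchange records
  under a deliberately high chamber deficit (25 °C at ~30 % RH gives
  D ≈ 2.2 kPa) taken as direct readings of the residual conductance.

* **Daytime conductance (g_d).** Day records qualify as a residual
  proxy only where net assimilation is at or below 1 μmol m⁻² s⁻¹
  (configurable threshold); above that the stomata are demonstrably
  open and g_d measures something else.

Treatment-level floors are defined positionally in the light × water
factorial: **g0** is the mean estimate in the well-watered deep-shade
cell (P0 × shade), **gmin** the mean in the droughted full-sun cell
(P80 × sun).

## The model family

All four forms share the Ball–Berry index x = A·RH/Ca and a slope m:

| form | equation | fitted parameters (k) |
|------|----------|----------------------|
| BB | gs = g_int + m·x | g_int, m (2) |
| BB_MEAS | gs = g_int + m·x, g_int measured | m (1) |
| BBD | gs = max[max(g0, gmin), m·x] | m (1) |
| BB_MIN | gs = max[min(g0, gmin), m·x] | m (1) |

Conductances are fitted in mol m⁻² s⁻¹ (floors quoted in mmol are
converted at the spec boundary); the humidity term is relative humidity
itself — no deficit-based variant is fitted, though the design leaves
that as an extension point. Records with negative assimilation
(respiration) are retained: the floored forms absorb them, and the
additive forms may predict below their intercept, as their equation
dictates. The BB intercept is not constrained to be positive by
default; `fit_model` exposes the choice implicitly because a negative
fitted intercept remains visible in the result rather than being
clipped.

BB is a closed-form OLS fit; BB_MEAS a slope-only fit through the
origin of (gs − g_int) on x. The floored forms have a piecewise-smooth
RSS(m), so m is found by a deterministic 500-point bracketing grid on
[0, 50] followed by golden-section refinement to 1e-8 — no gradient
methods near the kink. If every record sits in the floor-active regime
the slope is unidentifiable and fitting stops with an error.

Model comparison uses the Gaussian least-squares AIC,
n·ln(RSS/n) + 2(k+1), with the error variance counted as a parameter
and measured floors/intercepts counted as measurements, not parameters.
A model is labelled *more plausible* only when every rival is ≥ 2 AIC
units worse. Fits carry a checksum of their calibration records, and
`compare_models` refuses to rank fits made on different data. Observed-
vs-predicted regressions (observations on predictions) report slope,
intercept, R², and flag departures from (1, 0) at twice the standard
error. Calibration uses records measured under growth light
(sun 1500, shade 40 μmol m⁻² s⁻¹); records under swapped light levels
form the validation split, and diagnostics can be computed on either.

## Photosynthesis and the coupled solver

Assimilation follows the standard biochemical model: A = min(Ac, Aj) −
Rd, with Rubisco-limited Ac = Vcmax·(Ci − Γ\*)/(Ci + Kc(1 + O/Ko)) and
transport-limited Aj = J·(Ci − Γ\*)/(4Ci + 8Γ\*), J the smaller root of
θJ² − (αPAR + Jmax)J + αPAR·Jmax = 0. Kinetic constants and activation
energies default to the widely used in-vivo tobacco calibration
(Γ\*₂₅ = 42.75, Kc₂₅ = 404.9 μmol mol⁻¹, Ko₂₅ = 278.4 mmol mol⁻¹,
O = 210 mmol mol⁻¹); θ = 0.9 and α = 0.3 are common broadleaf values.
Vcmax and Jmax additionally carry a peaked (deactivating) temperature
response (Hd = 200 kJ mol⁻¹, ΔS = 650 J mol⁻¹ K⁻¹, optimum near 38 °C):
a bare Arrhenius response would keep capacity rising to 45 °C, which is
unphysical and would hide exactly the hot-leaf regime where the
conductance floor takes over. There is no triose-phosphate limitation
and no mesophyll conductance — Ci is the substrate concentration — and
the water-to-CO₂ diffusivity ratio is fixed at 1.6 with infinite
boundary-layer conductance.

`fit_aci` estimates (Vcmax, Jmax, Rd) from a stepped-CO₂ curve by
nonlinear least squares under the min-rule, with starts from closed-form
fits of the low- and high-Ci limbs, Levenberg–Marquardt refinement and a
Nelder–Mead polish across the non-smooth transition. Curves that never
leave one limitation regime are flagged ill-determined.

`solve_coupled` finds the Ci where biochemical demand equals diffusive
supply, A(Ci) = (gs/1.6)(Ca − Ci), with gs evaluated self-consistently
from the stomatal spec at the current candidate. Bisection runs on
Ci ∈ [1, 3·Ca] (≤ 200 iterations, returned residual < 1e-6
μmol m⁻² s⁻¹). One numerical subtlety: a respiring leaf with a very
small floor balances at Ci = Ca + 1.6·|A|/gs, which for gs ≈ 0.6
mmol m⁻² s⁻¹ lies far above 3·Ca. The solver therefore widens the upper
bracket once (to 50·Ca) when the base bracket shows no sign change, and
only then reports failure. During bracketing, an additive BB form can
transiently predict gs ≤ 0 at probe points far from the solution; the
probe value is clamped to a tiny positive conductance and only a
non-physical *solution* is an error.

## The simulation experiment

`simulate_response` sweeps light (default 0–1500 μmol m⁻² s⁻¹) or
temperature (10–45 °C, with relative humidity held fixed so the deficit
rises with warming) and tabulates A, gs, Ci and E_l = gs·D/P per spec
per grid point, annotating per-point solver failures rather than
aborting the sweep.

The headline contrast — a daytime-derived floor of 20.3 vs a
drying-curve floor of 5.5 mmol m⁻² s⁻¹ — is simulated for a severely
water-stressed sun leaf (Vcmax₂₅ = 15, Jmax₂₅ = 30, Rd₂₅ = 1
μmol m⁻² s⁻¹, chamber humidity 0.3), chosen so net assimilation sits
near 1 μmol m⁻² s⁻¹ at growth light, as reported for the leaves those
drought floors were measured on. Under these conditions the larger
floor yields strictly higher Ci at every light level above compensation
and strictly higher transpiration across the whole temperature sweep.
Two boundary behaviours are worth knowing and are asserted in the test
suite rather than hidden:

* below the light-compensation point the ordering *inverts* — with
  A < 0 the balance point is Ci = Ca + 1.6|A|/gs, so a larger floor
  pins Ci *closer* to ambient. The light grid therefore starts at
  50 μmol m⁻² s⁻¹, the domain of the ordering claim;
* wherever the index term m·A·RH/Ca exceeds both floors the two specs
  predict identical conductance and the curves coincide exactly; for
  an unstressed leaf this happens over most of the sweep.

## Synthetic data

The generators replace the study's unpublished raw measurements and
carry their ground truth as attributes:

* `gen_gas_exchange`: 2 species × 2 light × 3 water factorial, default
  5 replicates per cell, both measurement roles (growth/swapped light).
  The chamber is CO₂ 400 μmol mol⁻¹ at 30 °C; relative humidity jitters
  around the 30 % set point (sd 0.02, the realistic control precision of
  a portable system). Assimilation comes from the true coupled model,
  with water stress scaling photosynthetic capacity (P0/P50/P80 →
  1/0.55/0.25); observed gs adds Gaussian noise (default sd 0.005
  mol m⁻² s⁻¹). What this does *not* emulate: leaf-to-leaf parameter
  variation, sunfleck transients after the light swap, circadian
  nocturnal dynamics, or correlated instrument drift — so passing
  recovery tests demonstrate correctness of the estimators, not
  robustness to every field artefact.
* `gen_mass_loss_series`: strictly linear drying at the rate implied by
  the true conductance under constant deficit, plus weighing noise
  (default sd 0.5 mg). Real curves flatten as the leaf equilibrates;
  the constant-deficit idealisation is what makes the full-series
  window optimal here, and is stated wherever the estimates are used.
* `gen_aci_curve`: walks the stepped-CO₂ protocol (400, 300, …, 1500
  μmol mol⁻¹; the nominal 0 step emitted at 5 to keep the diffusion
  relation finite), solving the coupled model per set point and adding
  noise to A (default sd 0.5 μmol m⁻² s⁻¹).

Default residual-conductance cell means (sun 7.4/6.2/5.5, shade
4.0/3.1/5.0 mmol m⁻² s⁻¹ for P0/P50/P80) follow the pattern reported
for Mediterranean oaks: declining with drought in the sun, lowest in
well-watered shade. All generators are deterministic under a fixed
seed; there is no hidden global random state.

## Problem sizes and verification

The shipped tests and the acceptance script use the sizes that make the
statistics meaningful at desk scale: ~200 calibration records per
species for parameter recovery (sampling SE of the BB intercept ≈ 3.5 %,
so recovery within 5 % is asserted on the median of 11 replicate
simulations, not on a single draw); 100 seeded replicates for the
AIC-selection experiment; 1000 random parameterisations for the
coupled-solver/grid-oracle agreement (grid step 0.01 μmol mol⁻¹,
agreement within 0.02); 5-leaf treatment means for drying-curve
recovery under noise. The model-selection consistency property is
checked by doubling-plus the record count (~50 → ~300 per species) and
requiring the win fraction not to fall.

## Known limitations

* Leaf temperature is taken equal to block/air temperature; no energy
  balance, so the deficit driving transpiration is air-to-air.
* The residual conductance is a lumped quantity; cuticular loss and
  incomplete stomatal closure are not separated.
* No deficit-based humidity response, no Medlyn-style optimal models,
  no mixed-effects structure across leaves.
* The published per-model AIC values shipped in
  `inst/extdata/published_model_comparison.csv` are a transcription of
  a printed table used for delta-AIC arithmetic; the raw data behind
  them are not distributed, which is precisely why the synthetic
  generators exist.
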