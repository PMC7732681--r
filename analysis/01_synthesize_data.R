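#!/usr/bin/env Rscript
# Stage 1: generate the study's input data with known ground truth.
#
# No raw measurements are distributed with the study this pipeline
# models, so every downstream stage runs on synthetic data from the
# package's generators: a 2-species x 2-light x 3-water factorial of
# gas-exchange records (growth and swapped light roles), five drying
# curves per treatment cell, and one A/Ci curve per species.

library(stomres)

seed <- 20260929 %% 100000
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# species A: a floored (BBD) stomatal truth; species B: an additive (BB)
# truth — so later model selection has one of each to find
design <- synthetic_design(
  species = c("species_A", "species_B"),
  replicates = 5,
  true_specs = list(
    species_A = stomatal_spec("BBD", m = 9, g0 = 0.0055, gmin = 0.0055,
                              floor_source = "MLD"),
    species_B = stomatal_spec("BB", m = 9, gint = 0.0089)),
  true_params = list(
    species_A = fvcb_params(Vcmax25 = 60, Jmax25 = 120, Rd25 = 1),
    species_B = fvcb_params(Vcmax25 = 75, Jmax25 = 140, Rd25 = 1.2)))

records <- gen_gas_exchange(design, seed = seed)
write_gas_exchange_table(records, file.path(out, "gas_exchange.csv"))
cat("gas exchange:", nrow(records), "records ->",
    file.path(out, "gas_exchange.csv"), "\n")

# drying curves: five leaves per treatment cell, true conductance at the
# design's cell means
air <- air_state(25, 0.30, 101.325)
curve_meta <- list()
k <- 0
for (sp in design$species) {
  for (i in seq_len(nrow(design$gres_cells))) {
    cell <- design$gres_cells[i, ]
    for (leaf in 1:5) {
      k <- k + 1
      s <- gen_mass_loss_series(cell$gres_mmol, area = 1e-3, air = air,
                                noise_sd = 5e-4, seed = seed + k)
      f <- sprintf("drying_%s_%s_%s_leaf%d.csv", sp, cell$light,
                   cell$water, leaf)
      write.csv(data.frame(time_s = s$times, mass_g = s$masses),
                file.path(out, f), row.names = FALSE)
      curve_meta[[k]] <- data.frame(
        file = f, species = sp, light = cell$light, water = cell$water,
        leaf = leaf, g_res_true_mmol = cell$gres_mmol, area_m2 = 1e-3,
        T_air_C = air$T_air, RH_frac = air$RH, P_kPa = air$P_atm)
    }
  }
}
meta <- do.call(rbind, curve_meta)
write.csv(meta, file.path(out, "drying_manifest.csv"), row.names = FALSE)
cat("drying curves:", k, "leaves ->", out, "\n")

# A/Ci curves at the stepped-CO2 protocol
for (sp in design$species) {
  curve <- gen_aci_curve(design$true_params[[sp]], noise_sd = 0.5,
                         seed = seed + match(sp, design$species))
  write.csv(curve, file.path(out, paste0("aci_", sp, ".csv")),
            row.names = FALSE)
}
cat("A/Ci curves written for", length(design$species), "species\n")

# ground truth sidecar for later stages
truth <- data.frame(
  species = design$species,
  form = vapply(design$true_specs, `[[`, character(1), "form"),
  m = vapply(design$true_specs, `[[`, numeric(1), "m"),
  floor_or_gint_mol = vapply(design$true_specs, function(s)
    if (s$form == "BB") s$gint else max(s$g0, s$gmin), numeric(1)))
write.csv(truth, file.path(out, "ground_truth.csv"), row.names = FALSE)
cat("ground truth ->", file.path(out, "ground_truth.csv"), "\n")
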