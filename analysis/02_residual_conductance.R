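#!/usr/bin/env Rscript
# Stage 2: estimate residual conductance from the drying curves and
# derive the treatment-level floor candidates.
#
# Each leaf's weighing log is inverted to a water-loss flux (ordinary
# least squares of mass on time) and then to a conductance via
# g = E P / D. Per-leaf estimates are averaged within treatment cells;
# g0 is the well-watered deep-shade cell (P0 x shade) and gmin the
# droughted full-sun cell (P80 x sun).

library(stomres)

dat <- "results/data"
out <- "results"
stopifnot(file.exists(file.path(dat, "drying_manifest.csv")))
manifest <- read.csv(file.path(dat, "drying_manifest.csv"))

per_leaf <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
  m <- manifest[i, ]
  air <- air_state(m$T_air_C, m$RH_frac, m$P_kPa)
  s <- read_mass_loss_csv(file.path(dat, m$file), m$area_m2, air)
  est <- gmld_from_series(s, window = "full")
  cbind(m[c("species", "light", "water", "leaf", "g_res_true_mmol")], est)
}))
write.csv(per_leaf, file.path(out, "gmld_per_leaf.csv"), row.names = FALSE)

cat("per-leaf residual conductance (mmol m-2 s-1):\n")
cell_means <- aggregate(gmld_mmol ~ species + light + water, per_leaf, mean)
truth <- aggregate(g_res_true_mmol ~ species + light + water, per_leaf,
                   unique)
cell_means$truth <- truth$g_res_true_mmol
cell_means$err_pct <- with(cell_means,
                           100 * (gmld_mmol - truth) / truth)
print(cell_means, digits = 3)
cat("largest cell-mean error:",
    sprintf("%.2f%%", max(abs(cell_means$err_pct))), "\n\n")

estimates <- data.frame(value = per_leaf$gmld_mmol, method = "MLD",
                        species = per_leaf$species,
                        light = per_leaf$light, water = per_leaf$water)
floors <- assign_g0_gmin(estimates, "MLD")
write.csv(floors, file.path(out, "floors_g0_gmin.csv"), row.names = FALSE)
cat("treatment-derived floors (mmol m-2 s-1):\n")
print(floors, digits = 3)
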