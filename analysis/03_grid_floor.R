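#!/usr/bin/env Rscript
# Step 3 — matched-model localization.
# With the reference forward model and low sensor noise, every constraint and
# both localization criteria should recover the displaced nearest node, i.e.
# a localization error inside the (0.5, 0.6) mm grid-offset band.

suppressPackageStartupMessages(library(beamcascade))
dir.create("results", showWarnings = FALSE)

cfg <- experiment_config(
  modality = "eeg", n_reference_sources = 12, n_nodes = 300,
  perturbation_levels = 0,
  constraints = c("unit_gain", "unit_array_gain", "unit_noise_gain"),
  criteria = c("variance", "kurtosis"),
  orientation_classes = c("quasi_tangential", "quasi_radial"),
  noise_levels = c(low = 1e-3),
  master_seed = 1, geometry_seed = 42
)
tab <- run_experiment(cfg)
write.csv(tab, "results/grid_floor_rows.csv", row.names = FALSE)

ok <- tab$error > 0.5 & tab$error < 0.6
cat(sprintf("rows: %d | in grid-offset band: %d (%.0f%%)\n",
            nrow(tab), sum(ok), 100 * mean(ok)))
agg <- aggregate(error ~ constraint + criterion, tab, median)
print(agg, digits = 3)
if (all(ok)) {
  cat("matched-model localization is floor-limited for every source,\n")
  cat("constraint, criterion and orientation class.\n")
} else {
  cat("WARNING: some rows exceeded the grid-offset band:\n")
  print(tab[!ok, c("source", "orientation_class", "constraint", "criterion", "error")])
}
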