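#!/usr/bin/env Rscript
# Step 5 — report.
# Renders the cascade summaries as Tukey-style boxplot panels (median-anchored
# whiskers, 40 mm display cap) and prints the headline comparisons.

suppressPackageStartupMessages(library(beamcascade))
summ <- read.csv("results/cascade_summary.csv")
dir.create("results/figures", showWarnings = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  p <- plot_error_summaries(summ)
  ggplot2::ggsave("results/figures/cascade_boxplots.png", p,
                  width = 11, height = 7, dpi = 150)
  cat("figure written to results/figures/cascade_boxplots.png\n")
}

cat("\n== headline comparisons ==\n")
v <- subset(summ, criterion == "variance" & model == "perturb_0.2")
for (nl in unique(v$noise)) {
  vv <- subset(v, noise == nl)
  cat(sprintf("highest mismatch, %s noise: medians (mm): %s\n", nl,
              paste(sprintf("%s=%.1f", vv$constraint, vv$median), collapse = ", ")))
}
k <- subset(summ, model == "perturb_0.2" & noise == "high" & constraint == "unit_array_gain")
if (nrow(k) == 2) {
  cat(sprintf("kurtosis vs variance median at highest mismatch: %.2f vs %.2f mm\n",
              k$median[k$criterion == "kurtosis"], k$median[k$criterion == "variance"]))
}
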