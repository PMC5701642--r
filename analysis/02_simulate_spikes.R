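#!/usr/bin/env Rscript
# Step 2 — spike simulation.
# Builds the biphasic interictal-spike template (530 ms, 636 samples at
# 1200 Hz), assembles a 20 s single-source measurement with two firings at
# 100 nAm, and adds the protocol's low/high white sensor noise.

suppressPackageStartupMessages(library(beamcascade))
dir.create("results/measurements", recursive = TRUE, showWarnings = FALSE)

wave <- make_spike_waveform()
cat(sprintf("spike template: %d samples (%.0f ms at %g Hz), peak %.3f\n",
            length(wave$samples), wave$duration, wave$rate, max(abs(wave$samples))))
write.table(data.frame(t_ms = (seq_along(wave$samples) - 0.5) / wave$rate * 1000,
                       amplitude = wave$samples),
            "results/measurements/spike_template.tsv", sep = "\t", row.names = FALSE)

shells <- make_shell_model("reference")
eeg <- eeg_sensor_array(shells = shells)
meg <- meg_sensor_array(shells = shells)
refs <- make_reference_sources(60, radius = 70, seed = 42)
src <- 1
ori <- reference_orientations(meg_sphere_leadfield(meg, refs[src, ]))$quasi_tangential
gcol <- as.numeric(lf_gain(compute_leadfields(refs[src, , drop = FALSE], eeg, shells), 1) %*% ori)

base <- assemble_measurement(gcol, wave, onsets = c(6001L, 15601L),
                             duration = 20, rate = 1200, amplitude = 100,
                             modality = "eeg",
                             truth = list(source = src, orientation = ori))
cat(sprintf("measurement: %d channels x %d samples, peak signal %.2f µV\n",
            base$n_channels, base$n_samples, max(abs(base$data))))

for (nl in c(low = 1e-3, high = 1)) {
  name <- names(which(c(low = 1e-3, high = 1) == nl))
  m <- demean_channels(common_average_reference(add_white_noise(base, nl, seed = 7)))
  snr <- max(rowMeans(base$data^2)) / nl
  cat(sprintf("  %s noise (%g µV²): peak channel signal-power/noise ratio %.1f\n",
              name, nl, snr))
  write_measurement_bundle(m, file.path("results/measurements", paste0("eeg_", name)))
}
cat("measurement bundles written to results/measurements/\n")
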