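# Small shared fixtures, built in code at test time.

fixture_shells <- function() make_shell_model("reference")

# A tiny EEG setup: few electrodes, few nodes, two reference sources.
fixture_eeg_setup <- function(n_nodes = 60, n_refs = 3, seed = 7) {
  shells <- fixture_shells()
  refs <- make_reference_sources(n_refs, seed = seed)
  space <- build_source_space(n_nodes, shells, refs, seed = seed + 1)
  eeg <- eeg_sensor_array(32, shells = shells)
  meg <- meg_sensor_array(48, shells = shells)
  list(shells = shells, refs = refs, space = space, eeg = eeg, meg = meg)
}

# Random positive-definite covariance object of dimension N.
fixture_covariance <- function(N, seed) {
  M <- with_seed_test(seed, {
    A <- matrix(rnorm(3 * N * N), 3 * N, N)
    crossprod(A) / (3 * N)
  })
  sample_covariance_from_matrix(M)
}

# Build a bf_covariance directly from a covariance matrix by synthesizing a
# data matrix would be awkward; instead exploit that sample_covariance of
# B = R' * sqrt(T) ... simpler: construct via the exported constructor on a
# factor: if M = F F' / T then sample_covariance(F) has matrix M.
sample_covariance_from_matrix <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  F <- e$vectors %*% diag(sqrt(pmax(e$values, 0) * ncol(M)))
  sample_covariance(F) # (1/T) F F' = M with T = N columns
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Standard protocol pieces used across tests.
fixture_measurement <- function(setup, source = 1, orientation_class = "quasi_tangential",
                                noise = 1e-3, seed = 123, modality = "eeg") {
  sensors <- if (modality == "eeg") setup$eeg else setup$meg
  ref_lf <- compute_leadfields(setup$refs, sensors, setup$shells)
  ori <- reference_orientations(
    meg_sphere_leadfield(setup$meg, setup$refs[source, ])
  )[[orientation_class]]
  gcol <- as.numeric(lf_gain(ref_lf, source) %*% ori)
  m <- assemble_measurement(gcol, make_spike_waveform(), c(6001L, 15601L),
                            modality = modality)
  if (noise > 0) m <- add_white_noise(m, noise, seed)
  if (modality == "eeg") m <- common_average_reference(m)
  demean_channels(m)
}
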