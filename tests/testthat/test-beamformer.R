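test_that("the sample covariance is the 1/T outer-product average", {
  expect_equal(sample_covariance(matrix(c(1, -1), 1, 2))$matrix, matrix(1, 1, 1))
  expect_true(all(sample_covariance(matrix(0, 3, 5))$matrix == 0))
  set.seed(11)
  B <- matrix(rnorm(6 * 40), 6, 40)
  B <- B - rowMeans(B)
  expect_equal(sample_covariance(B)$matrix, oracle_covariance(B), tolerance = 1e-12)
  expect_error(sample_covariance(matrix(1, 3, 1)), "two time samples")
})

test_that("Frobenius normalization is exact and idempotent", {
  g <- frobenius_normalize(diag(3))
  expect_equal(diag(g), rep(1 / sqrt(3), 3))
  set.seed(2)
  m <- matrix(rnorm(30), 10, 3)
  n1 <- frobenius_normalize(m)
  expect_equal(sqrt(sum(n1^2)), 1, tolerance = 1e-14)
  expect_equal(frobenius_normalize(n1), n1, tolerance = 1e-14)
  expect_error(frobenius_normalize(matrix(0, 4, 3)), "zero")
})

test_that("excess kurtosis matches its defining moment ratio and bounds", {
  expect_identical(excess_kurtosis(rep(c(1, -1), 50)), -2)
  expect_equal(excess_kurtosis(1:5), -1.3, tolerance = 1e-14)
  expect_equal(excess_kurtosis(1:5), oracle_kurtosis(1:5), tolerance = 1e-15)
  set.seed(8)
  x <- rnorm(1e6)
  expect_lt(abs(excess_kurtosis(x)), 0.02) # Gaussian: zero excess kurtosis
  # affine invariance g2(aX + b) = g2(X)
  y <- rexp(500)
  expect_equal(excess_kurtosis(-3.2 * y + 11), excess_kurtosis(y), tolerance = 1e-10)
  expect_error(excess_kurtosis(rep(5, 10)), "zero sample variance")
  expect_error(excess_kurtosis(c(1, 2)), "4 samples")
})

test_that("constrained weights satisfy their identities and closed-form relations", {
  set.seed(21)
  N <- 16
  C <- fixture_covariance(N, seed = 22)
  L <- rnorm(N)
  w_ug <- lcmv_weights(L, C, "unit_gain")
  w_uag <- lcmv_weights(L, C, "unit_array_gain")
  w_ung <- lcmv_weights(L, C, "unit_noise_gain")
  expect_equal(sum(w_ug * L), 1, tolerance = 1e-10)
  expect_equal(sum(w_uag * L), sqrt(sum(L^2)), tolerance = 1e-10)
  expect_equal(sum(w_ung^2), 1, tolerance = 1e-10)
  expect_gt(sum(w_ung * L), 0)
  expect_equal(w_uag, sqrt(sum(L^2)) * w_ug, tolerance = 1e-10)
  expect_equal(w_ung, w_ug / sqrt(sum(w_ug^2)), tolerance = 1e-10)
  # identity covariance collapses the unit-gain filter to L / (L'L)
  CI <- sample_covariance_from_matrix(diag(N))
  expect_equal(lcmv_weights(L, CI, "unit_gain"), L / sum(L^2), tolerance = 1e-10)
})

test_that("variance-optimal orientations beat a dense direction grid", {
  U <- oracle_direction_grid(4000)
  set.seed(33)
  for (k in 1:8) {
    gain <- matrix(rnorm(36), 12, 3)
    Cobj <- fixture_covariance(12, seed = 300 + k)
    for (ct in c("unit_gain", "unit_array_gain", "unit_noise_gain")) {
      u <- optimal_orientation(gain, Cobj, ct)
      v_opt <- oracle_constraint_variance(gain, Cobj$matrix, rbind(u), ct)
      v_grid <- max(oracle_constraint_variance(gain, Cobj$matrix, U, ct))
      expect_gte(v_opt, v_grid * (1 - 1e-6))
    }
  }
})

test_that("orientation degeneracies resolve to documented choices", {
  set.seed(5)
  # rank-1 gain: only one admissible direction
  d <- unit_vec <- c(1, 2, -2) / 3
  gain <- outer(rnorm(10), d)
  Cobj <- fixture_covariance(10, seed = 6)
  u <- optimal_orientation(gain, Cobj, "unit_array_gain")
  expect_gt(abs(sum(u * d)), 1 - 1e-8)
  # identity covariance: unit-noise-gain pencil degenerate -> top singular vector
  gain2 <- matrix(rnorm(30), 10, 3)
  CI <- sample_covariance_from_matrix(diag(10))
  u2 <- optimal_orientation(gain2, CI, "unit_noise_gain")
  sv <- svd(gain2)
  expect_gt(abs(sum(u2 * sv$v[, 1])), 1 - 1e-8)
  expect_error(optimal_orientation(matrix(0, 10, 3), Cobj), "zero")
})

test_that("the unit-gain filter passes matched noiseless sources distortion-free", {
  setup <- fixture_eeg_setup(n_nodes = 20, n_refs = 2)
  ref_lf <- compute_leadfields(setup$refs, setup$eeg, setup$shells)
  ori <- reference_orientations(meg_sphere_leadfield(setup$meg, setup$refs[1, ]))$quasi_tangential
  gcol <- as.numeric(lf_gain(ref_lf, 1) %*% ori)
  w <- make_spike_waveform()
  m <- demean_channels(assemble_measurement(gcol, w, c(6001L, 15601L), modality = "eeg"))
  C <- sample_covariance(m, loading = 1e-8) # rank-1 data need loading
  f <- make_filter(lf_gain(ref_lf, 1), C, "unit_gain")
  y <- as.numeric(t(f$weights) %*% m$data)
  # W'L = 1 for the normalized gain: y reconstructs the source waveform up to
  # the Frobenius scale of the gain and the sign of the estimated orientation
  src <- m$data[which.max(abs(gcol)), ] / gcol[which.max(abs(gcol))]
  scale <- as.numeric(crossprod(y, src) / crossprod(src, src))
  expect_lt(max(abs(y - scale * src)) / max(abs(scale * src)), 1e-6)
})

test_that("variance output equals the direct time-series variance", {
  set.seed(41)
  B <- matrix(rnorm(8 * 200), 8, 200)
  B <- B - rowMeans(B)
  w <- rnorm(8)
  y <- as.numeric(t(w) %*% B)
  expect_equal(variance_output(w, B), mean((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(variance_output(3 * w, B), 9 * variance_output(w, B), tolerance = 1e-10)
  # orthogonal filter passes nothing
  Br <- outer(c(1, 0, 0, 0, 0, 0, 0, 0), rnorm(50))
  expect_equal(variance_output(c(0, 1, 0, 0, 0, 0, 0, 0), Br), 0)
})

test_that("scans cover every node, respect the kurtosis bound and flag degeneracies", {
  setup <- fixture_eeg_setup(n_nodes = 40, n_refs = 2)
  lf <- compute_leadfields(setup$space, setup$eeg, setup$shells)
  m <- fixture_measurement(setup, noise = 1e-3)
  sc <- beamformer_scan(setup$space, lf, m, "unit_array_gain")
  expect_equal(nrow(sc), 40)
  expect_true(all(sc$kurtosis_output[!sc$skipped] >= -2))
  expect_true(all(sc$variance_output[!sc$skipped] >= 0))
  # a zeroed node is skipped with a warning, not silently zeroed
  lf_bad <- lf
  lf_bad$gain[, 4:6] <- 0
  expect_warning(sc_bad <- beamformer_scan(setup$space, lf_bad, m, "unit_array_gain"),
                 "skipped")
  expect_true(sc_bad$skipped[2])
  expect_true(is.na(sc_bad$variance_output[2]))
})

test_that("kurtosis maps are scale-invariant across constraints at fixed orientation", {
  # rank-1 gains force identical orientations, so unit-gain and array-gain
  # filters differ only by scale and g2 must agree
  setup <- fixture_eeg_setup(n_nodes = 12, n_refs = 2)
  lf <- compute_leadfields(setup$space, setup$eeg, setup$shells)
  set.seed(9)
  for (i in seq_len(12)) { # collapse each node's gain to rank 1
    cols <- (3 * i - 2):(3 * i)
    d <- unit(rnorm(3))
    lf$gain[, cols] <- outer(lf$gain[, cols] %*% d, d)
  }
  m <- fixture_measurement(setup, noise = 1e-3)
  s_ug <- beamformer_scan(setup$space, lf, m, "unit_gain")
  s_uag <- beamformer_scan(setup$space, lf, m, "unit_array_gain")
  expect_equal(s_ug$kurtosis_output, s_uag$kurtosis_output, tolerance = 1e-8)
})
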