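test_that("the spike template has the protocol length and a normalized biphasic shape", {
  w <- make_spike_waveform(rate = 1200, duration = 530)
  expect_length(w$samples, 636)
  expect_equal(max(abs(w$samples)), 1)
  expect_lt(abs(w$samples[1]), 0.01) # starts and ends near zero
  expect_lt(abs(w$samples[length(w$samples)]), 0.01)
  expect_lt(min(w$samples), 0) # biphasic: both polarities present
  expect_gt(max(w$samples), 0)
  expect_length(make_spike_waveform(rate = 1000, duration = 100)$samples, 100)
  expect_error(make_spike_waveform(rate = -1), "rate")
  expect_error(make_spike_waveform(duration = 0), "duration")
})

test_that("assembled measurements place scaled spikes in an otherwise zero recording", {
  w <- make_spike_waveform()
  gcol <- c(1, -2, 0.5)
  m <- assemble_measurement(gcol, w, onsets = c(6001L, 15601L),
                            duration = 20, rate = 1200, amplitude = 100,
                            modality = "eeg")
  expect_equal(m$n_samples, 24000)
  inside <- c(6001:6636, 15601:16236)
  expect_true(all(m$data[, -inside] == 0))
  # peak µV equals gain * 100 nAm * unit conversion
  expect_equal(max(abs(m$data)), 2 * 100 * 1e-3, tolerance = 1e-12)
  expect_true(all(assemble_measurement(gcol, w, 100L, amplitude = 0)$data == 0))
  expect_error(assemble_measurement(gcol, w, c(100L, 300L)), "overlap")
  expect_error(assemble_measurement(gcol, w, 23999L), "inside")
  # superposition: two sources add exactly
  m1 <- assemble_measurement(c(1, 0, 0), w, 101L)
  m2 <- assemble_measurement(c(0, 2, 0), w, 5001L)
  m12a <- m1$data + m2$data
  expect_identical(m12a[1, ], assemble_measurement(c(1, 0, 0), w, 101L)$data[1, ])
})

test_that("white noise is rescaled to the exact variance and shares one realization across scales", {
  w <- make_spike_waveform()
  m0 <- assemble_measurement(c(1, -1, 2, 0.5), w, 6001L)
  m_lo <- add_white_noise(m0, 1e-3, seed = 99)
  noise_lo <- m_lo$data - m0$data
  v <- rowMeans((noise_lo - rowMeans(noise_lo))^2)
  expect_equal(v, rep(1e-3, 4), tolerance = 1e-12)
  m_hi <- add_white_noise(m0, 1, seed = 99)
  noise_hi <- m_hi$data - m0$data
  expect_equal(noise_hi, noise_lo * sqrt(1000), tolerance = 1e-12)
  expect_identical(add_white_noise(m0, 0, seed = 1), m0)
  expect_error(add_white_noise(m0, -1, seed = 1), ">= 0")
  # determinism across calls
  expect_identical(add_white_noise(m0, 1e-3, seed = 99)$data, m_lo$data)
})

test_that("demeaning and common-average referencing are exact", {
  w <- make_spike_waveform()
  m <- add_white_noise(assemble_measurement(c(1, -1, 2), w, 6001L), 0.5, seed = 4)
  md <- demean_channels(m)
  expect_lt(max(abs(rowMeans(md$data))) / max(apply(md$data, 1, sd)), 1e-12)
  # constant channel becomes all-zero
  m$data[2, ] <- 7
  expect_true(all(demean_channels(m)$data[2, ] == 0))
  mc <- common_average_reference(m)
  expect_lt(max(abs(colMeans(mc$data))), 1e-12 * max(abs(mc$data)))
})
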