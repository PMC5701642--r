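# Simulated interictal-spike measurements: biphasic spike template, two
# firings in a 20 s recording, and white sensor noise at stated variances.

#' Parametric biphasic interictal-spike template
#'
#' A difference-of-Gaussians template emulating an averaged interictal spike:
#' a sharp transient followed by a slower wave of opposite sign. The template
#' is dimensionless, peak-normalized to 1 in absolute value, and starts and
#' ends at (numerically) zero amplitude. Defaults give the protocol template:
#' 530 ms at 1200 samples/s, i.e. 636 samples.
#'
#' @param rate sampling rate in samples/s (> 0).
#' @param duration template duration in ms (> 0).
#' @param shape_params list with elements `t_spike`, `w_spike`, `t_wave`,
#'   `w_wave` (ms) and `wave_fraction` (relative slow-wave amplitude).
#' @return An object of class `spike_waveform` with fields `samples`, `rate`,
#'   `duration`.
#' @export
#' @examples
#' w <- make_spike_waveform()
#' length(w$samples) # 636
make_spike_waveform <- function(rate = 1200, duration = 530,
                                shape_params = list(
                                  t_spike = 130, w_spike = 15,
                                  t_wave = 300, w_wave = 55,
                                  wave_fraction = 0.45
                                )) {
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  n <- round(rate * duration / 1000)
  t <- (seq_len(n) - 0.5) / rate * 1000 # ms
  p <- shape_params
  s <- -exp(-(t - p$t_spike)^2 / (2 * p$w_spike^2)) +
    p$wave_fraction * exp(-(t - p$t_wave)^2 / (2 * p$w_wave^2))
  s <- s / max(abs(s))
  structure(list(samples = s, rate = rate, duration = duration),
            class = "spike_waveform")
}

new_measurement <- function(data, rate, modality, units, truth = NULL) {
  structure(
    list(data = data, rate = rate, modality = modality, units = units,
         n_channels = nrow(data), n_samples = ncol(data), truth = truth),
    class = "measurement"
  )
}

#' @export
print.measurement <- function(x, ...) {
  cat("<measurement>", x$n_channels, toupper(x$modality), "channels x",
      x$n_samples, "samples @", x$rate, "Hz;", x$units, "\n")
  invisible(x)
}

#' Assemble a noiseless single-source measurement
#'
#' Inserts the amplitude-scaled spike template at each onset on top of an
#' otherwise zero measurement: `data = gain_column %*% (amplitude * waveform)`
#' within each spike window. Units are µV for EEG (gain in V/(A*m)) and fT for
#' MEG (gain in T/(A*m)); `amplitude` is the peak source strength in nAm.
#'
#' @param gain_column numeric vector: the source's leadfield along its moment
#'   direction, one value per channel.
#' @param waveform a [make_spike_waveform()] template.
#' @param onsets spike onset sample indices (1-based), non-overlapping.
#' @param duration total measurement duration in seconds.
#' @param rate sampling rate in samples/s (defaults to the template's).
#' @param amplitude peak source amplitude in nAm (default 100).
#' @param modality `"eeg"` or `"meg"`.
#' @param truth optional extra fields recorded in the truth annotation.
#' @return A `measurement` with a populated `truth` record.
#' @export
assemble_measurement <- function(gain_column, waveform, onsets, duration = 20,
                                 rate = waveform$rate, amplitude = 100,
                                 modality = c("eeg", "meg"), truth = list()) {
  modality <- match.arg(modality)
  stopifnot(inherits(waveform, "spike_waveform"))
  n_total <- round(rate * duration)
  wlen <- length(waveform$samples)
  onsets <- as.integer(onsets)
  if (any(onsets < 1) || any(onsets + wlen - 1L > n_total)) {
    stop("spike windows must lie inside the measurement", call. = FALSE)
  }
  if (length(onsets) > 1) {
    o <- sort(onsets)
    if (any(diff(o) < wlen)) stop("spike windows must not overlap", call. = FALSE)
  }
  # nAm * V/(A*m) = 1e-9 V = 1e-3 µV; nAm * T/(A*m) = 1e-9 T = 1e6 fT
  unit_scale <- if (modality == "eeg") 1e-3 else 1e6
  units <- if (modality == "eeg") "µV" else "fT"
  src <- numeric(n_total)
  for (o in onsets) src[o:(o + wlen - 1L)] <- src[o:(o + wlen - 1L)] + waveform$samples
  data <- outer(as.numeric(gain_column), src * amplitude * unit_scale)
  new_measurement(
    data, rate, modality, units,
    truth = c(list(onsets = onsets, amplitude_nAm = amplitude,
                   waveform_samples = wlen), truth)
  )
}

#' Add scaled white sensor noise
#'
#' Adds per-channel independent Gaussian noise whose realized sample variance
#' is rescaled to equal `variance` exactly on every channel. The underlying
#' unit realization depends only on `(seed, shape)`, so two calls with the
#' same seed and variances `v` and `1000 v` produce noise matrices related by
#' the exact factor `sqrt(1000)` — one shared noise realization, just
#' rescaled.
#'
#' @param meas a `measurement`.
#' @param variance noise variance in the measurement's units squared (>= 0).
#' @param seed integer seed.
#' @return The measurement with noise added.
#' @export
add_white_noise <- function(meas, variance, seed) {
  stopifnot(inherits(meas, "measurement"))
  if (!is.numeric(variance) || length(variance) != 1 || variance < 0) {
    stop("`variance` must be a single number >= 0", call. = FALSE)
  }
  if (variance == 0) return(meas)
  noise <- unit_noise_realization(meas$n_channels, meas$n_samples, seed)
  meas$data <- meas$data + sqrt(variance) * noise
  meas$truth$noise_variance <- variance
  meas$truth$noise_seed <- seed
  meas
}

# White-noise realization with exactly unit sample variance (1/T moments) per
# channel, deterministic in (seed, shape). Cached so that the same realization
# is reused across noise scales within a session.
unit_noise_realization <- function(n_channels, n_samples, seed) {
  key <- sprintf("%d_%d_%d", seed, n_channels, n_samples)
  cached <- .noise_cache[[key]]
  if (!is.null(cached)) return(cached)
  raw <- with_seed(seed, matrix(stats::rnorm(n_channels * n_samples), n_channels, n_samples))
  m <- rowMeans(raw)
  v <- rowMeans((raw - m)^2)
  out <- raw / sqrt(v)
  if (length(.noise_cache) > 8) rm(list = ls(.noise_cache), envir = .noise_cache)
  .noise_cache[[key]] <- out
  out
}
.noise_cache <- new.env(parent = emptyenv())

#' Remove each channel's temporal mean
#'
#' The beamformer formulation assumes zero-mean data at every sensor.
#'
#' @param meas a `measurement`.
#' @return The measurement with exactly zero-mean channels.
#' @export
demean_channels <- function(meas) {
  stopifnot(inherits(meas, "measurement"))
  meas$data <- meas$data - rowMeans(meas$data)
  meas
}

#' Re-reference an EEG measurement to the common average
#'
#' Subtracts the instantaneous mean over electrodes from every sample. Signal
#' generated through a common-average-referenced leadfield already satisfies
#' this; sensor noise is added per electrode and physically precedes
#' referencing, so the assembled measurement is re-referenced as a whole.
#'
#' @param meas an EEG `measurement`.
#' @return The re-referenced measurement.
#' @export
common_average_reference <- function(meas) {
  stopifnot(inherits(meas, "measurement"))
  if (meas$modality != "eeg") stop("common average reference applies to EEG", call. = FALSE)
  meas$data <- sweep(meas$data, 2, colMeans(meas$data))
  meas
}
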