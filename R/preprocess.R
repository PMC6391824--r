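#' Preprocessing configuration
#'
#' The filter chain applied to every channel before kinematic derivation:
#' sensor-bias removal, a 10 Hz low-pass, then a 6th-order Butterworth
#' band-pass. Both filters are applied forward-backward (zero phase) so
#' peak timing is preserved.
#'
#' @param lowpass_cutoff_hz low-pass cutoff (Hz); default 10.
#' @param bandpass_low_hz,bandpass_high_hz band-pass edges (Hz).
#' @param bandpass_order overall band-pass filter order (even); default 6.
#' @param lowpass_order low-pass filter order; default 6.
#' @param remove_bias subtract each channel's mean first.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(lowpass_cutoff_hz = 10, bandpass_low_hz = 2,
                              bandpass_high_hz = 5, bandpass_order = 6,
                              lowpass_order = 6, remove_bias = TRUE) {
  cfg <- list(
    lowpass_cutoff_hz = lowpass_cutoff_hz,
    bandpass_low_hz = bandpass_low_hz,
    bandpass_high_hz = bandpass_high_hz,
    bandpass_order = as.integer(bandpass_order),
    lowpass_order = as.integer(lowpass_order),
    remove_bias = isTRUE(remove_bias)
  )
  if (!(cfg$bandpass_low_hz > 0 &&
        cfg$bandpass_low_hz < cfg$bandpass_high_hz)) {
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  }
  if (cfg$bandpass_order < 2 || cfg$bandpass_order %% 2 != 0) {
    stop("bandpass_order must be an even integer >= 2", call. = FALSE)
  }
  if (cfg$lowpass_order < 1) stop("lowpass_order must be >= 1", call. = FALSE)
  class(cfg) <- "preprocess_config"
  cfg
}

check_band <- function(sampling_rate_hz, low_hz, high_hz) {
  nyq <- sampling_rate_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop(sprintf(
      "band [%g, %g] Hz must lie strictly inside (0, %g) Hz (Nyquist)",
      low_hz, high_hz, nyq), call. = FALSE)
  }
}

# Causal IIR filtering (direct form, zero initial conditions) via two
# C-level stats::filter passes: FIR convolution then AR recursion.
causal_filter <- function(b, a, x) {
  nb <- length(b)
  xz <- c(rep(0, nb - 1), x)
  v <- stats::filter(xz, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xz)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1] / a[1], method = "recursive"))
  }
  v / a[1]
}

# Filter around the sequence's initial level: the filter sees a signal
# starting at zero (no start-up step) and the level re-enters through the
# DC gain, so constants map to constants exactly and start-up transients
# stay small. The operator remains linear.
causal_filter_dc <- function(b, a, x) {
  g <- sum(b) / sum(a)
  c0 <- x[1]
  causal_filter(b, a, x - c0) + c0 * g
}

# Zero-phase forward-backward filtering with odd-reflection padding of
# 3 x order samples at each end (the reflection preserves level and slope,
# suppressing edge transients while keeping the operator linear).
filt_zero_phase <- function(b, a, x, order) {
  n <- length(x)
  pad <- 3L * order
  if (n < pad + 1) {
    stop(sprintf("sequence too short (%d samples) for order-%d zero-phase filtering",
                 n, order), call. = FALSE)
  }
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  y <- causal_filter_dc(b, a, xp)
  y <- rev(causal_filter_dc(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the given overall order (a 6th-order
#' band-pass arises from a 3rd-order low-pass prototype) and applies it
#' forward and backward, squaring the magnitude response and cancelling the
#' phase.
#'
#' @param x numeric sequence.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param low_hz,high_hz band edges (Hz), strictly inside (0, Nyquist).
#' @param order overall filter order (even).
#' @return Filtered sequence, same length as `x`.
#' @export
butterworth_bandpass <- function(x, sampling_rate_hz, low_hz = 2,
                                 high_hz = 5, order = 6) {
  check_band(sampling_rate_hz, low_hz, high_hz)
  order <- as.integer(order)
  if (order < 2 || order %% 2 != 0) {
    stop("band-pass order must be an even integer >= 2", call. = FALSE)
  }
  if (length(x) < 3 * order) {
    stop(sprintf("sequence of length %d is too short for order %d",
                 length(x), order), call. = FALSE)
  }
  filt <- signal::butter(order %/% 2,
                         c(low_hz, high_hz) / (sampling_rate_hz / 2),
                         type = "pass")
  filt_zero_phase(filt$b, filt$a, x, order)
}

#' Zero-phase Butterworth low-pass filter
#'
#' @inheritParams butterworth_bandpass
#' @param cutoff_hz cutoff frequency (Hz), inside (0, Nyquist).
#' @return Filtered sequence, same length as `x`.
#' @export
lowpass <- function(x, sampling_rate_hz, cutoff_hz = 10, order = 6) {
  nyq <- sampling_rate_hz / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq)) {
    stop(sprintf("cutoff %g Hz must lie in (0, %g) Hz", cutoff_hz, nyq),
         call. = FALSE)
  }
  order <- as.integer(order)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  if (length(x) < 3 * order) {
    stop(sprintf("sequence of length %d is too short for order %d",
                 length(x), order), call. = FALSE)
  }
  filt <- signal::butter(order, cutoff_hz / nyq, type = "low")
  filt_zero_phase(filt$b, filt$a, x, order)
}

#' Remove constant sensor bias
#'
#' Subtracts the mean, so constant offsets such as gravity on the
#' accelerometer Z channel or a gyroscope zero-rate offset vanish.
#'
#' @param x numeric sequence of length >= 1.
#' @return `x - mean(x)`.
#' @export
remove_bias <- function(x) {
  if (length(x) < 1) stop("cannot remove bias from an empty sequence",
                          call. = FALSE)
  x - mean(x)
}

#' Squared magnitude response of the zero-phase band-pass
#'
#' Evaluates |H(e^{j omega})|^2 of the designed digital Butterworth
#' band-pass at the given frequencies (the square reflecting the
#' forward-backward application), directly from the filter polynomials.
#'
#' @param freqs_hz frequencies at which to evaluate (Hz).
#' @inheritParams butterworth_bandpass
#' @return Vector of squared-magnitude gains.
#' @export
bandpass_response_squared <- function(freqs_hz, sampling_rate_hz, low_hz = 2,
                                      high_hz = 5, order = 6) {
  check_band(sampling_rate_hz, low_hz, high_hz)
  filt <- signal::butter(order %/% 2,
                         c(low_hz, high_hz) / (sampling_rate_hz / 2),
                         type = "pass")
  w <- 2 * pi * freqs_hz / sampling_rate_hz
  z <- exp(-1i * w)
  H <- vapply(z, function(zz) {
    num <- sum(filt$b * zz^(seq_along(filt$b) - 1))
    den <- sum(filt$a * zz^(seq_along(filt$a) - 1))
    Mod(num / den)
  }, numeric(1))
  H^2
}

#' Apply the full preprocessing chain to a recording
#'
#' Per channel: bias removal, 10 Hz low-pass, Butterworth band-pass (all
#' zero-phase). Returns a recording of identical shape.
#'
#' @param recording an [imu_recording()].
#' @param config a [preprocess_config()].
#' @return A preprocessed [imu_recording()].
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "imu_recording"),
            inherits(config, "preprocess_config"))
  fs <- recording$sampling_rate_hz
  check_band(fs, config$bandpass_low_hz, config$bandpass_high_hz)
  proc <- function(x) {
    if (config$remove_bias) x <- remove_bias(x)
    x <- lowpass(x, fs, config$lowpass_cutoff_hz, config$lowpass_order)
    butterworth_bandpass(x, fs, config$bandpass_low_hz,
                         config$bandpass_high_hz, config$bandpass_order)
  }
  imu_recording(
    accel = apply(recording$accel, 2, proc),
    gyro = apply(recording$gyro, 2, proc),
    sampling_rate_hz = fs
  )
}
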