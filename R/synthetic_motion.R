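#' Motion-simulation parameters
#'
#' Phenomenological model of the alternating oscillatory limb movement seen
#' in the three bedside coordination tests. The movement is a sinusoid whose
#' frequency and amplitude are redrawn every cycle (cycle-to-cycle
#' variability being a hallmark of ataxic movement), plus an optional tremor
#' harmonic, white sensor noise, a constant gyroscope bias and gravity on
#' the accelerometer Z channel.
#'
#' @param base_freq_hz dominant alternation frequency (Hz).
#' @param freq_jitter_sd cycle-to-cycle frequency standard deviation (Hz).
#' @param amplitude peak value of the primary channel (deg/s for gyroscope
#'   channels, m/s^2 for accelerometer channels).
#' @param amplitude_jitter_sd relative cycle-to-cycle amplitude s.d.
#' @param tremor_freq_hz tremor frequency (Hz); 0 disables tremor.
#' @param tremor_amp_ratio tremor amplitude as a fraction of `amplitude`
#'   (must be < 1).
#' @param noise_sd white sensor-noise s.d. applied to every channel.
#' @param gyro_bias constant offset added to every gyroscope channel (deg/s).
#' @param include_gravity add +9.81 to the accelerometer Z channel.
#' @param duration_s recording duration (s).
#' @param primary_channel one of `"ax","ay","az","gx","gy","gz"`; the channel
#'   carrying the movement at full amplitude. All other channels receive an
#'   attenuated cross-talk copy (factor `crosstalk`).
#' @param crosstalk attenuation of the movement on secondary channels.
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(base_freq_hz, freq_jitter_sd = 0, amplitude = 1,
                          amplitude_jitter_sd = 0, tremor_freq_hz = 0,
                          tremor_amp_ratio = 0, noise_sd = 0, gyro_bias = 0,
                          include_gravity = TRUE, duration_s = 15,
                          primary_channel = "gy", crosstalk = 0.2) {
  p <- list(
    base_freq_hz = base_freq_hz, freq_jitter_sd = freq_jitter_sd,
    amplitude = amplitude, amplitude_jitter_sd = amplitude_jitter_sd,
    tremor_freq_hz = tremor_freq_hz, tremor_amp_ratio = tremor_amp_ratio,
    noise_sd = noise_sd, gyro_bias = gyro_bias,
    include_gravity = isTRUE(include_gravity), duration_s = duration_s,
    primary_channel = primary_channel, crosstalk = crosstalk
  )
  class(p) <- "motion_params"
  p
}

validate_motion_params <- function(params, sampling_rate_hz) {
  stopifnot(inherits(params, "motion_params"))
  with(params, {
    if (!is.finite(base_freq_hz) || base_freq_hz <= 0 ||
        base_freq_hz >= sampling_rate_hz / 2) {
      stop("base_freq_hz must lie in (0, sampling_rate/2)", call. = FALSE)
    }
    if (freq_jitter_sd < 0 || amplitude_jitter_sd < 0 || noise_sd < 0 ||
        tremor_freq_hz < 0 || tremor_amp_ratio < 0) {
      stop("jitter, tremor and noise parameters must be nonnegative",
           call. = FALSE)
    }
    if (tremor_amp_ratio >= 1) {
      stop("tremor_amp_ratio must be < 1", call. = FALSE)
    }
    if (amplitude <= 0) stop("amplitude must be positive", call. = FALSE)
    if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
    if (duration_s * sampling_rate_hz < 64) {
      stop("duration x sampling rate must give at least 64 samples",
           call. = FALSE)
    }
    if (!primary_channel %in% REC_COLUMNS) {
      stop(sprintf("unknown primary channel '%s'", primary_channel),
           call. = FALSE)
    }
  })
  invisible(params)
}

# Per-test, per-severity presets. Patients move more slowly and more
# variably than controls, with a tremor harmonic appearing at higher
# severity; amplitudes are held constant across classes (the class signal
# is carried by tempo and variability, not vigour). These presets are
# configuration, not clinical claims.
PRESET_TABLE <- list(
  FNT = list(base = c(1.2, 0.9, 0.7), amplitude = 120, channel = "gy"),
  DDK = list(base = c(3.6, 2.9, 2.3), amplitude = 250, channel = "gy"),
  HST = list(base = c(0.8, 0.6, 0.5), amplitude = 3.0, channel = "az")
)
PRESET_JITTER_REL <- c(0.02, 0.06, 0.12)   # of base, severity 0/1/2
PRESET_TREMOR_RATIO <- c(0, 0.1, 0.25)

#' Default motion parameters for a test and severity class
#'
#' Presets encode the qualitative clinical picture: dominant frequency
#' strictly decreases and cycle-to-cycle variability strictly increases with
#' severity. The primary channel is the pronation-supination gyroscope Y
#' axis for the upper-limb tests (FNT, DDK) and the accelerometer Z axis for
#' the heel-to-shin test, where linear motion dominates.
#'
#' @param test `"FNT"`, `"DDK"` or `"HST"`.
#' @param severity 0 (control), 1 (mild) or 2 (significant ataxia).
#' @return A [motion_params()] object.
#' @export
default_params <- function(test, severity) {
  test <- match.arg(test, TESTS)
  severity <- as.integer(severity)
  if (is.na(severity) || !severity %in% 0:2) {
    stop("severity must be 0, 1 or 2", call. = FALSE)
  }
  preset <- PRESET_TABLE[[test]]
  i <- severity + 1L
  base <- preset$base[i]
  motion_params(
    base_freq_hz = base,
    freq_jitter_sd = PRESET_JITTER_REL[i] * base,
    amplitude = preset$amplitude,
    amplitude_jitter_sd = PRESET_JITTER_REL[i],
    tremor_freq_hz = 2 * base,
    tremor_amp_ratio = PRESET_TREMOR_RATIO[i],
    noise_sd = 0.02 * preset$amplitude,
    gyro_bias = 1.0,
    include_gravity = TRUE,
    duration_s = 15,
    primary_channel = preset$channel
  )
}

# Piecewise-constant-frequency oscillation: each cycle draws its own
# frequency and amplitude; phase is continuous across cycle boundaries.
# All RNG draws have a data-independent count so a fixed seed is
# reproducible bitwise.
synth_primary_signal <- function(params, t) {
  base <- params$base_freq_hz
  # enough cycles to cover the duration even under extreme upward jitter
  n_cycles <- ceiling(params$duration_s * (base + 8 * params$freq_jitter_sd)) + 8L
  freqs <- base + stats::rnorm(n_cycles, 0, params$freq_jitter_sd)
  freqs <- pmax(freqs, 0.1 * base)
  amps <- params$amplitude *
    pmax(1 + stats::rnorm(n_cycles, 0, params$amplitude_jitter_sd), 0.05)
  bounds <- c(0, cumsum(1 / freqs))
  if (bounds[n_cycles + 1] < params$duration_s) {
    # deterministic extension at the base frequency (no extra RNG)
    extra <- ceiling((params$duration_s - bounds[n_cycles + 1]) * base) + 2L
    freqs <- c(freqs, rep(base, extra))
    amps <- c(amps, rep(params$amplitude, extra))
    bounds <- c(0, cumsum(1 / freqs))
  }
  k <- findInterval(t, bounds, rightmost.closed = FALSE)
  k <- pmin(pmax(k, 1L), length(freqs))
  phase <- 2 * pi * ((k - 1) + (t - bounds[k]) * freqs[k])
  amps[k] * sin(phase)
}

#' Simulate one labelled IMU test session
#'
#' Generates a [test_session()] whose primary channel carries the jittered
#' oscillation plus tremor and noise; all other channels carry an attenuated
#' cross-talk copy plus noise. Gravity is added to accelerometer Z and a
#' constant bias to the gyroscope channels, so downstream bias removal is
#' exercised. Deterministic for a fixed seed.
#'
#' @param test,limb,severity session metadata (see [test_session()]).
#' @param params a [motion_params()]; defaults to
#'   `default_params(test, severity)`.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param seed integer RNG seed.
#' @param subject_id subject identifier for the session.
#' @return A [test_session()].
#' @export
simulate_session <- function(test, limb, severity,
                             params = default_params(test, severity),
                             sampling_rate_hz = 50, seed,
                             subject_id = "synthetic") {
  validate_motion_params(params, sampling_rate_hz)
  n <- round(params$duration_s * sampling_rate_hz)
  t <- (seq_len(n) - 1) / sampling_rate_hz
  channels <- with_seed(seed, {
    s <- synth_primary_signal(params, t)
    tremor_phase <- stats::runif(1, 0, 2 * pi)
    if (params$tremor_amp_ratio > 0 && params$tremor_freq_hz > 0) {
      s <- s + params$tremor_amp_ratio * params$amplitude *
        sin(2 * pi * params$tremor_freq_hz * t + tremor_phase)
    }
    out <- matrix(0, nrow = n, ncol = 6,
                  dimnames = list(NULL, REC_COLUMNS))
    for (ch in REC_COLUMNS) {
      gain <- if (ch == params$primary_channel) 1 else params$crosstalk
      noise <- if (params$noise_sd > 0) {
        stats::rnorm(n, 0, params$noise_sd)
      } else {
        numeric(n)
      }
      out[, ch] <- gain * s + noise
    }
    out
  })
  if (params$include_gravity) channels[, "az"] <- channels[, "az"] + 9.81
  channels[, c("gx", "gy", "gz")] <-
    channels[, c("gx", "gy", "gz")] + params$gyro_bias
  test_session(
    subject_id = subject_id, test = test, limb = limb, severity = severity,
    recording = imu_recording(
      accel = channels[, c("ax", "ay", "az")],
      gyro = channels[, c("gx", "gy", "gz")],
      sampling_rate_hz = sampling_rate_hz
    )
  )
}

#' Simulate a labelled cohort for one test
#'
#' Generates both limbs for every subject. Each subject draws an individual
#' movement tempo and vigour around the class preset (relative s.d.
#' `subject_sd`), emulating inter-individual variability; per-subject and
#' per-limb seeds are derived deterministically from the master seed.
#'
#' @param n_per_class integer triple: number of subjects with severity
#'   0, 1 and 2.
#' @param test `"FNT"`, `"DDK"` or `"HST"`.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param seed master RNG seed.
#' @param subject_sd relative between-subject s.d. of base frequency and
#'   amplitude.
#' @param params_fun function `(test, severity) -> motion_params` supplying
#'   the class presets; defaults to [default_params()].
#' @return An [ataxia_dataset()] with `2 * sum(n_per_class)` sessions.
#' @export
simulate_cohort <- function(n_per_class, test, sampling_rate_hz = 50, seed,
                            subject_sd = 0.06,
                            params_fun = default_params) {
  test <- match.arg(test, TESTS)
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 3 || any(is.na(n_per_class)) ||
      any(n_per_class < 0)) {
    stop("n_per_class must be three nonnegative integers", call. = FALSE)
  }
  n_total <- sum(n_per_class)
  if (n_total == 0) stop("empty cohort: all class counts are zero",
                         call. = FALSE)
  subject_seeds <- derive_seeds(seed, n_total)
  severities <- rep(0:2, times = n_per_class)
  sessions <- vector("list", 2L * n_total)
  for (i in seq_len(n_total)) {
    sev <- severities[i]
    base_params <- params_fun(test, sev)
    sid <- sprintf("subj%03d", i)
    subj <- with_seed(subject_seeds[i], {
      list(
        freq_factor = max(1 + stats::rnorm(1, 0, subject_sd), 0.5),
        amp_factor = max(1 + stats::rnorm(1, 0, subject_sd), 0.5),
        limb_seeds = sample.int(.Machine$integer.max - 1L, 2)
      )
    })
    p <- base_params
    p$base_freq_hz <- min(p$base_freq_hz * subj$freq_factor,
                          0.49 * sampling_rate_hz)
    p$freq_jitter_sd <- p$freq_jitter_sd * subj$freq_factor
    p$amplitude <- p$amplitude * subj$amp_factor
    p$tremor_freq_hz <- 2 * p$base_freq_hz
    for (j in 1:2) {
      sessions[[2L * (i - 1L) + j]] <- simulate_session(
        test = test, limb = LIMBS[j], severity = sev, params = p,
        sampling_rate_hz = sampling_rate_hz, seed = subj$limb_seeds[j],
        subject_id = sid
      )
    }
  }
  ataxia_dataset(sessions)
}
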