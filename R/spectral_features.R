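#' One-sided FFT magnitude spectrum
#'
#' The mean is removed and the signal zero-padded to the next power of two
#' at least four times its length, giving resonant-frequency granularity of
#' at most `fs / (4 n)`. Magnitudes are raw one-sided DFT moduli
#' (no 2/N normalisation; any constant factor cancels in cohort
#' comparisons).
#'
#' @param x numeric sequence, length >= 64.
#' @param sampling_rate_hz sampling rate (Hz).
#' @return An object of class `imu_spectrum` with `freqs_hz`, `magnitudes`
#'   and `n_fft`.
#' @export
fft_spectrum <- function(x, sampling_rate_hz) {
  n <- length(x)
  if (n < 64) stop(sprintf("sequence too short (%d samples; need >= 64)", n),
                   call. = FALSE)
  xc <- x - mean(x)
  n_fft <- 2^ceiling(log2(4 * n))
  X <- stats::fft(c(xc, rep(0, n_fft - n)))
  half <- n_fft / 2 + 1
  structure(
    list(
      freqs_hz = (seq_len(half) - 1) * sampling_rate_hz / n_fft,
      magnitudes = Mod(X[seq_len(half)]),
      n_fft = n_fft,
      sampling_rate_hz = sampling_rate_hz
    ),
    class = "imu_spectrum"
  )
}

#' Resonant frequency and magnitude at resonance
#'
#' Locates the largest-magnitude bin inside the search band. Ties are broken
#' toward the lowest frequency (reading direction: slower = more affected).
#'
#' @param spectrum an [fft_spectrum()] result.
#' @param band_hz numeric pair `(low, high)`; band within (0, Nyquist].
#' @return List with `rf_hz` (resonant frequency) and `mr` (its magnitude).
#' @export
resonant_peak <- function(spectrum, band_hz = c(0.25, 5)) {
  stopifnot(inherits(spectrum, "imu_spectrum"))
  nyq <- spectrum$sampling_rate_hz / 2
  if (!(band_hz[1] > 0 && band_hz[1] < band_hz[2] && band_hz[2] <= nyq)) {
    stop(sprintf("search band [%g, %g] must lie within (0, %g] Hz",
                 band_hz[1], band_hz[2], nyq), call. = FALSE)
  }
  idx <- which(spectrum$freqs_hz >= band_hz[1] &
                 spectrum$freqs_hz <= band_hz[2])
  if (length(idx) == 0) stop("search band contains no frequency bin",
                             call. = FALSE)
  mags <- spectrum$magnitudes[idx]
  if (max(mags) <= 0) stop("no spectral peak in band (zero spectrum)",
                           call. = FALSE)
  i <- idx[which.max(mags)]  # which.max -> first maximum -> lowest frequency
  list(rf_hz = spectrum$freqs_hz[i], mr = spectrum$magnitudes[i])
}

feature_name <- function(kind, test, limb, axis, measure) {
  sprintf("%s_%s(%s)^{%s,%s}", kind, test, limb, axis, measure)
}

#' The 60-feature frequency-domain vector for one subject and test
#'
#' For each limb (L, R), kinematic measure (A, V, Av, Aa, An) and axis
#' (X, Y, Z), the FFT resonant frequency (RF) and magnitude at resonance
#' (MR) are extracted: 2 x 5 x 3 x 2 = 60 named features, e.g.
#' `"RF_DDK(L)^{Y,Av}"`.
#'
#' @param left,right [derive_kinematics()] results for the left and right
#'   limb.
#' @param test `"FNT"`, `"DDK"` or `"HST"`.
#' @param band_hz resonant-peak search band (Hz).
#' @param subject_id optional identifier attached to the result.
#' @return A named numeric vector of length 60 with class
#'   `feature_vector` and attributes `test` and `subject_id`.
#' @export
extract_feature_vector <- function(left, right, test, band_hz = c(0.25, 5),
                                   subject_id = NA_character_) {
  test <- match.arg(test, TESTS)
  if (!inherits(left, "kinematic_set") || !inherits(right, "kinematic_set")) {
    stop("both left and right kinematic sets are required", call. = FALSE)
  }
  sets <- list(L = left, R = right)
  values <- numeric(0)
  for (limb in LIMBS) {
    ks <- sets[[limb]]
    for (measure in MEASURES) {
      for (axis in AXES) {
        spec <- fft_spectrum(ks[[measure]][, axis], ks$sampling_rate_hz)
        peak <- tryCatch(
          resonant_peak(spec, band_hz),
          error = function(e) {
            stop(sprintf("feature %s: %s",
                         feature_name("RF", test, limb, axis, measure),
                         conditionMessage(e)), call. = FALSE)
          }
        )
        values[feature_name("RF", test, limb, axis, measure)] <- peak$rf_hz
        values[feature_name("MR", test, limb, axis, measure)] <- peak$mr
      }
    }
  }
  stopifnot(length(values) == 60, !anyDuplicated(names(values)))
  structure(values, class = "feature_vector", test = test,
            subject_id = subject_id)
}

#' Normalised spectral entropy
#'
#' Shannon entropy of the Hann-windowed one-sided power spectrum,
#' normalised by the log of the bin count, so a pure tone scores near 0 and
#' white noise near 1. Invariant to signal scaling.
#'
#' @param x numeric sequence, length >= 64.
#' @param sampling_rate_hz sampling rate (Hz).
#' @return A value in \[0, 1\].
#' @export
spectral_entropy <- function(x, sampling_rate_hz) {
  n <- length(x)
  if (n < 64) stop("sequence too short for spectral entropy", call. = FALSE)
  xc <- x - mean(x)
  if (all(xc == 0)) stop("spectral entropy undefined for a constant signal",
                         call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann
  X <- stats::fft(xc * w)
  half <- floor(n / 2) + 1
  p <- Mod(X[seq_len(half)])^2
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(half)
}

#' Dynamic time warping distance
#'
#' Classic DTW with absolute-difference local cost, unconstrained warping
#' window and the symmetric step pattern (match, insert, delete).
#'
#' @param a,b non-empty numeric sequences.
#' @return Nonnegative accumulated warping cost.
#' @export
dtw_distance <- function(a, b) {
  n <- length(a)
  m <- length(b)
  if (n == 0 || m == 0) stop("DTW requires non-empty sequences", call. = FALSE)
  cost <- abs(outer(a, b, `-`))
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- cost[i, j] +
        min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  D[n + 1, m + 1]
}

#' Maximum of the Welch-averaged power spectral density
#'
#' Welch's method with Hann-windowed segments of length 128 and 50 %
#' overlap on the mean-removed signal. The peak frequency is attached as
#' attribute `freq_hz`.
#'
#' @param x numeric sequence, length >= 128.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param segment_length samples per Welch segment.
#' @return Maximum PSD value with attribute `freq_hz`.
#' @export
psd_welch_max <- function(x, sampling_rate_hz, segment_length = 128) {
  n <- length(x)
  if (n < segment_length) {
    stop(sprintf("sequence too short (%d samples; need >= %d)", n,
                 segment_length), call. = FALSE)
  }
  xc <- x - mean(x)
  step <- segment_length %/% 2
  starts <- seq(1, n - segment_length + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(segment_length) - 1) /
                         (segment_length - 1))
  scale <- sampling_rate_hz * sum(w^2)
  half <- segment_length %/% 2 + 1
  acc <- numeric(half)
  for (s in starts) {
    seg <- xc[s:(s + segment_length - 1)] * w
    P <- Mod(stats::fft(seg))^2 / scale
    P1 <- P[seq_len(half)]
    P1[2:(half - 1)] <- 2 * P1[2:(half - 1)]  # one-sided doubling
    acc <- acc + P1
  }
  psd <- acc / length(starts)
  freqs <- (seq_len(half) - 1) * sampling_rate_hz / segment_length
  structure(max(psd), freq_hz = freqs[which.max(psd)])
}

#' Feature matrix for every complete limb pair of a dataset
#'
#' Preprocesses each session, derives kinematics, and extracts the
#' 60-feature vector per subject. One row per subject, columns
#' `subject_id`, `severity`, then the 60 canonical feature names.
#'
#' @param dataset an [ataxia_dataset()].
#' @param test which test's sessions to use.
#' @param preprocess a [preprocess_config()] (or `NULL` to skip filtering
#'   and only remove bias).
#' @param band_hz resonant-peak search band (Hz).
#' @return A data frame of dimension n_subjects x 62.
#' @export
features_from_dataset <- function(dataset, test,
                                  preprocess = preprocess_config(),
                                  band_hz = c(0.25, 5)) {
  pairs <- session_pairs(dataset, test)
  if (length(pairs) == 0) stop(sprintf("no '%s' sessions in dataset", test),
                               call. = FALSE)
  rows <- lapply(pairs, function(pr) {
    prep <- function(rec) {
      if (is.null(preprocess)) {
        imu_recording(apply(rec$accel, 2, remove_bias),
                      apply(rec$gyro, 2, remove_bias),
                      rec$sampling_rate_hz)
      } else {
        preprocess_recording(rec, preprocess)
      }
    }
    fv <- extract_feature_vector(
      left = derive_kinematics(prep(pr$L$recording)),
      right = derive_kinematics(prep(pr$R$recording)),
      test = test, band_hz = band_hz, subject_id = pr$subject_id
    )
    cbind(data.frame(subject_id = pr$subject_id, severity = pr$severity,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(fv)), check.names = FALSE,
                        optional = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Numeric feature matrix from a [features_from_dataset()] data frame
#'
#' Drops the `subject_id` and `severity` columns and sets subject ids as
#' row names.
#'
#' @param features_df data frame from [features_from_dataset()].
#' @return Numeric subjects x features matrix.
#' @export
as_feature_matrix <- function(features_df) {
  m <- as.matrix(features_df[, setdiff(colnames(features_df),
                                       c("subject_id", "severity")),
                             drop = FALSE])
  rownames(m) <- features_df$subject_id
  m
}
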