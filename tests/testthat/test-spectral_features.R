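fs <- 50
tt <- (0:749) / fs

test_that("fft_spectrum locates tones and zeroes degenerate input", {
  x <- sin(2 * pi * 3 * tt)
  spec <- fft_spectrum(x, fs)
  expect_gte(spec$n_fft, 4 * length(x))
  bin <- fs / spec$n_fft
  expect_equal(diff(spec$freqs_hz[1:2]), bin)
  peak <- spec$freqs_hz[which.max(spec$magnitudes)]
  grid <- seq(0.25, 10, by = bin)
  expect_lt(abs(peak - oracle_dtft_peak(x, fs, grid)), bin + 1e-12)
  expect_lt(abs(peak - 3), bin)

  expect_true(all(fft_spectrum(numeric(100), fs)$magnitudes == 0))
  expect_true(all(fft_spectrum(rep(2.5, 100), fs)$magnitudes < 1e-10))
  expect_error(fft_spectrum(numeric(10), fs), "too short")
})

test_that("resonant_peak respects the band, tie rule and error contract", {
  x <- sin(2 * pi * 3 * tt)
  spec <- fft_spectrum(x, fs)
  pk <- resonant_peak(spec, c(0.25, 10))
  expect_equal(pk$rf_hz, 3, tolerance = fs / spec$n_fft)
  expect_equal(pk$mr, max(spec$magnitudes))

  # manual spectrum with two exactly equal peaks: lowest frequency wins
  manual <- structure(list(freqs_hz = seq(0, 25, by = 0.5),
                           magnitudes = rep(0, 51), n_fft = 100,
                           sampling_rate_hz = fs), class = "imu_spectrum")
  manual$magnitudes[manual$freqs_hz == 3] <- 7
  manual$magnitudes[manual$freqs_hz == 4] <- 7
  expect_equal(resonant_peak(manual, c(0.5, 10))$rf_hz, 3)

  zero <- structure(list(freqs_hz = manual$freqs_hz,
                         magnitudes = rep(0, 51), n_fft = 100,
                         sampling_rate_hz = fs), class = "imu_spectrum")
  expect_error(resonant_peak(zero, c(0.5, 10)), "no spectral peak")
  expect_error(resonant_peak(spec, c(5, 40)), "within")
})

kin_pair <- function(seed, test = "DDK") {
  mk <- function(s) {
    rec <- s$recording
    derive_kinematics(imu_recording(apply(rec$accel, 2, remove_bias),
                                    apply(rec$gyro, 2, remove_bias), fs))
  }
  list(L = mk(simulate_session(test, "L", 0, sampling_rate_hz = fs,
                               seed = seed)),
       R = mk(simulate_session(test, "R", 0, sampling_rate_hz = fs,
                               seed = seed + 1)))
}

test_that("the feature vector has exactly 60 canonically named entries", {
  kp <- kin_pair(10)
  fv <- extract_feature_vector(kp$L, kp$R, "DDK", c(0.25, 5))
  expect_length(fv, 60)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_true(all(c("RF_DDK(L)^{Y,Av}", "MR_DDK(R)^{Z,A}") %in% names(fv)))
  expect_true(all(grepl("^(RF|MR)_DDK\\((L|R)\\)\\^\\{(X|Y|Z),(A|V|Av|Aa|An)\\}$",
                        names(fv))))
  rf <- fv[grepl("^RF", names(fv))]
  expect_true(all(rf >= 0.25 & rf <= 5))
  expect_true(all(fv[grepl("^MR", names(fv))] >= 0))
})

test_that("swapping limbs swaps exactly the limb tag of every entry", {
  kp <- kin_pair(20)
  ab <- extract_feature_vector(kp$L, kp$R, "DDK")
  ba <- extract_feature_vector(kp$R, kp$L, "DDK")
  # swap only the limb tag, leaving the RF/MR prefix untouched
  swapped <- gsub("\\(L\\)", "(#)", names(ab))
  swapped <- gsub("\\(R\\)", "(L)", swapped)
  swapped <- gsub("\\(#\\)", "(R)", swapped)
  expect_equal(as.numeric(ab), as.numeric(ba[match(swapped, names(ba))]))
})

test_that("resonant magnitude scales linearly with amplitude", {
  f1 <- simulate_session("DDK", "L", 0, clean_params(3, 100), fs, seed = 4)
  f2 <- simulate_session("DDK", "L", 0, clean_params(3, 200), fs, seed = 4)
  m1 <- resonant_peak(fft_spectrum(f1$recording$gyro[, "Y"], fs))$mr
  m2 <- resonant_peak(fft_spectrum(f2$recording$gyro[, "Y"], fs))$mr
  expect_equal(m2 / m1, 2, tolerance = 1e-6)
})

test_that("spectral entropy separates tones from noise and ignores scale", {
  tone <- sin(2 * pi * 3 * tt)
  expect_lte(spectral_entropy(tone, fs), 0.2)
  noise_h <- sapply(1:10, function(s) {
    set.seed(s)
    spectral_entropy(rnorm(4096), fs)
  })
  expect_gte(mean(noise_h), 0.9)
  expect_equal(spectral_entropy(7.3 * tone, fs),
               spectral_entropy(tone, fs), tolerance = 1e-12)
  expect_error(spectral_entropy(rep(1, 100), fs), "constant")
})

test_that("DTW matches direct evaluation and exhaustive path enumeration", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(0, 0), 1), 2)
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(sample(2:6, 1))
    b <- rnorm(sample(2:6, 1))
    expect_equal(dtw_distance(a, b), oracle_dtw(a, b), tolerance = 1e-12)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
  }
  expect_error(dtw_distance(numeric(0), 1), "non-empty")
})

test_that("Welch PSD peak tracks tone power and frequency", {
  tone <- sin(2 * pi * 3 * tt)
  big <- psd_welch_max(tone, fs)
  small <- psd_welch_max(0.5 * tone, fs)
  expect_gt(as.numeric(big), as.numeric(small))
  expect_equal(as.numeric(psd_welch_max(numeric(256), fs)), 0)
  expect_lt(abs(attr(big, "freq_hz") - 3), fs / 128 + 1e-12)
  expect_error(psd_welch_max(numeric(64), fs), "too short")
})
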