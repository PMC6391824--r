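# Independent brute-force oracles used to cross-check the package's
# implementations. Each is written from the defining formula, not from the
# code path it checks.

# Naive DTFT magnitude on an explicit frequency grid; argmax = peak.
oracle_dtft_peak <- function(x, fs, freqs) {
  x <- x - mean(x)
  t <- (seq_along(x) - 1) / fs
  mags <- vapply(freqs, function(f) {
    Mod(sum(x * exp(-2i * pi * f * t)))
  }, numeric(1))
  freqs[which.max(mags)]
}

# Analog Butterworth band-pass squared-magnitude curve, with bilinear
# prewarping of the probe and edge frequencies (the design's frequency
# mapping), squared once more for forward-backward application.
oracle_butter_bp_mag2 <- function(f, fs, lo, hi, order) {
  n <- order / 2  # low-pass prototype order
  W <- tan(pi * f / fs)
  Wl <- tan(pi * lo / fs)
  Wh <- tan(pi * hi / fs)
  x <- (W^2 - Wl * Wh) / (W * (Wh - Wl))
  1 / (1 + x^(2 * n))
}

# Silhouette by the definition, double loop, explicit Euclidean distances.
oracle_silhouette <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (cl in unique(labels[labels != labels[i]])) {
      members <- which(labels == cl)
      b <- min(b, mean(vapply(members, function(j) d(i, j), numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# DTW by plain recursion (no memoisation) — exponential, tiny inputs only.
oracle_dtw <- function(a, b) {
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(abs(a[1] - b[1]))
    cands <- c(
      if (i > 1) rec(i - 1, j) else Inf,
      if (j > 1) rec(i, j - 1) else Inf,
      if (i > 1 && j > 1) rec(i - 1, j - 1) else Inf
    )
    abs(a[i] - b[j]) + min(cands)
  }
  rec(length(a), length(b))
}

# Pearson r from the covariance/variance definition.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Welch two-sample p-value from the t statistic and Welch-Satterthwaite
# degrees of freedom, using only the t-distribution tail.
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(t), df)
}

# AUC as the Mann-Whitney pairwise-comparison statistic U / (n1 * n0).
oracle_auc <- function(score, is_patient) {
  sp <- score[is_patient]
  sc <- score[!is_patient]
  u <- 0
  for (p in sp) for (c in sc) {
    u <- u + (p > c) + 0.5 * (p == c)
  }
  u / (length(sp) * length(sc))
}

# A jitter-, tremor- and noise-free motion parameter set.
clean_params <- function(base_freq_hz, amplitude = 100,
                         primary_channel = "gy", duration_s = 15) {
  motion_params(base_freq_hz = base_freq_hz, amplitude = amplitude,
                primary_channel = primary_channel, duration_s = duration_s,
                gyro_bias = 0, include_gravity = FALSE)
}
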