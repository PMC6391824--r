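# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user
# simulations.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Draw n child seeds from a master seed, each usable as a set.seed() input.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Remove the least-squares linear trend (intercept + slope) from a vector.
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2) return(x - mean(x))
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc * tc)
  x - mean(x) - slope * tc
}

rms <- function(x) sqrt(mean(x^2))
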