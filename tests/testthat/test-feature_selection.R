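test_that("cohort p-values follow the Welch oracle and error contracts", {
  expect_equal(cohort_pvalue(c(1, 2, 3, 1, 2, 3),
                             c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)), 1.0)
  x <- c(0, 0.1, -0.1, 0.05)
  y <- c(10, 10.1, 9.9, 10.05)
  p <- cohort_pvalue(c(x, y), rep(c(FALSE, TRUE), each = 4))
  expect_lt(p, 1e-6)
  expect_equal(p, oracle_welch_p(y, x), tolerance = 1e-9)
  expect_error(cohort_pvalue(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               "at least 2")
  # both groups constant and equal
  expect_equal(cohort_pvalue(rep(4, 6), rep(c(TRUE, FALSE), 3)), 1.0)
})

test_that("pearson_r matches the definition and rejects degenerate input", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

make_null_matrix <- function(n = 40, p = 8, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  list(X = X, scores = rep(0:2, length.out = n))
}

test_that("selection keeps what differs, reports r for everything", {
  nm <- make_null_matrix()
  X <- nm$X
  scores <- nm$scores
  # inject a real effect into f01; make f02 identical across cohorts
  X[, "f01"] <- X[, "f01"] + 3 * (scores > 0)
  X[, "f02"] <- rep(c(1, 2), length.out = nrow(X))
  sel <- select_features(X, clinical_scores = scores)
  expect_true("f01" %in% sel$kept)
  expect_false("f02" %in% sel$kept)
  expect_length(sel$correlations, ncol(X))
  expect_true(all(sel$p_values[sel$kept] < sel$alpha))
  expect_equal(sel$kept, sort(sel$kept))

  # vacuous thresholds keep everything (continuous features: p < 1 a.s.)
  all_kept <- select_features(nm$X, clinical_scores = scores, alpha = 1.0,
                              r_min = 0)
  expect_length(all_kept$kept, ncol(nm$X))
})

test_that("selection is monotone in alpha and affine-invariant in p", {
  nm <- make_null_matrix(seed = 2)
  alphas <- c(0.01, 0.05, 0.2, 1.0)
  kept <- lapply(alphas, function(a) {
    select_features(nm$X, clinical_scores = nm$scores, alpha = a)$kept
  })
  for (i in seq_len(length(alphas) - 1)) {
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  }
  p1 <- select_features(nm$X, clinical_scores = nm$scores)$p_values
  p2 <- select_features(nm$X * 3.7 + 11,
                        clinical_scores = nm$scores)$p_values
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("the injected class signal on the primary channel is recovered", {
  ds <- simulate_cohort(c(15, 15, 15), "DDK", 50, seed = 3)
  feats <- features_from_dataset(ds, "DDK")
  sel <- select_features(feats, clinical_scores = feats$severity)
  key <- c("RF_DDK(L)^{Y,Av}", "RF_DDK(R)^{Y,Av}")
  expect_true(all(key %in% sel$kept))
  expect_true(all(sel$strong[key]))
  expect_true(all(abs(sel$correlations[key]) >= 0.5))
})

test_that("a single feature's null rejection rate is binomially calibrated", {
  # independent cohorts, one feature each: the marginal type-I rate of the
  # Welch rule is alpha (whole-vector keep counts are over-dispersed
  # because features within a cohort share per-subject latent factors)
  short_null <- function(test, severity) {
    p <- default_params(test, 0)
    p$duration_s <- 8
    p
  }
  n_cohorts <- 30
  rejections <- sum(sapply(seq_len(n_cohorts), function(seed) {
    ds <- simulate_cohort(c(5, 5, 5), "DDK", 50, seed = 5000 + seed,
                          params_fun = short_null)
    feats <- features_from_dataset(ds, "DDK", preprocess = NULL)
    cohort_pvalue(feats[["MR_DDK(L)^{Y,V}"]], feats$severity > 0) < 0.05
  }))
  bounds <- qbinom(c(0.005, 0.995), n_cohorts, 0.05)
  expect_gte(rejections, bounds[1])
  expect_lte(rejections, bounds[2])
})

test_that("degenerate cohorts raise a group-size error", {
  nm <- make_null_matrix()
  expect_error(select_features(nm$X, clinical_scores = rep(0, nrow(nm$X))),
               "at least 2")
})
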