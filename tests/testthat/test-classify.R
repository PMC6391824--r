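test_that("PCA projection satisfies its algebraic identities", {
  # rank-1 data on a line
  t <- seq(-1, 1, length.out = 20)
  X <- cbind(a = 2 * t, b = -3 * t)
  pr <- pca_project(X)
  expect_equal(pr$explained_variance_ratio[1], 1, tolerance = 1e-9)

  set.seed(9)
  X <- matrix(rnorm(20 * 60), 20, 60,
              dimnames = list(NULL, sprintf("f%02d", 1:60)))
  pr <- pca_project(X)
  expect_equal(sum(pr$explained_variance_ratio), 1, tolerance = 1e-12)
  expect_true(all(diff(pr$explained_variance_ratio) <= 1e-12))
  # orthonormal loadings; full-rank reconstruction of the z-scored matrix
  expect_equal(crossprod(pr$loadings), diag(pr$n_components),
               tolerance = 1e-8, ignore_attr = TRUE)
  Z <- sweep(sweep(X, 2, pr$feature_means), 2, pr$feature_scales, "/")
  expect_equal(pr$scores %*% t(pr$loadings), Z, tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(pca_project(X, 25), "n_components")
  # component sign aside, scores are invariant under feature reordering
  pr2 <- pca_project(X[, sample(60)])
  agree <- abs(colSums(pr$scores[, 1:5] * pr2$scores[, 1:5]) /
                 colSums(pr$scores[, 1:5]^2))
  expect_equal(agree, rep(1, 5), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("silhouette agrees with the brute-force definition", {
  set.seed(10)
  # two tight clusters far apart
  pts <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
               matrix(rnorm(40, 100, 0.1), 20, 2))
  lab <- rep(1:2, each = 20)
  sv <- silhouette_value(pts, lab)
  expect_gte(sv, 0.95)
  expect_equal(sv, oracle_silhouette(pts, lab), tolerance = 1e-12)

  # random labels on one blob: no structure
  null_sv <- sapply(1:10, function(s) {
    set.seed(s)
    silhouette_value(matrix(rnorm(120), 60, 2), sample(1:3, 60, TRUE))
  })
  expect_lte(mean(null_sv), 0.05)

  # every point its own class contributes 0 by the singleton convention
  expect_equal(silhouette_value(matrix(rnorm(10), 5, 2), 1:5), 0)
  expect_error(silhouette_value(matrix(rnorm(10), 5, 2), rep(1, 5)),
               "single class")

  if (requireNamespace("cluster", quietly = TRUE)) {
    set.seed(11)
    pts <- matrix(rnorm(60), 30, 2)
    lab <- sample(1:3, 30, TRUE)
    ref <- mean(cluster::silhouette(lab, stats::dist(pts))[, "sil_width"])
    expect_equal(silhouette_value(pts, lab), ref, tolerance = 1e-9)
  }
})

three_clusters <- function(n = 10, sd = 0.01, seed = 12) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n, 0, sd), n, 2),
             matrix(rnorm(2 * n, 10, sd), n, 2),
             matrix(rnorm(2 * n, 20, sd), n, 2))
  colnames(X) <- c("u", "v")
  list(X = X, y = rep(0:2, each = n))
}

test_that("LDA separates well-separated classes and keeps its orientation", {
  cl <- three_clusters()
  fit <- lda_fit(cl$X, cl$y)
  expect_equal(mean(fit$predicted == cl$y), 1.0)
  expect_gte(fit$class_stats[["0"]]$mean, fit$class_stats[["2"]]$mean)
  expect_lte(ncol(fit$projections), 2)
  # class statistics are computed on training projections
  expect_equal(fit$class_stats[["1"]]$range,
               fit$class_stats[["1"]]$max - fit$class_stats[["1"]]$min)

  # duplicating every subject scales both scatters equally
  fit2 <- lda_fit(rbind(cl$X, cl$X), c(cl$y, cl$y))
  expect_equal(fit2$predicted, rep(fit$predicted, 2))

  expect_error(lda_fit(cl$X[c(1, 11, 12, 21, 22), ],
                       c(0, 1, 1, 2, 2)), "class")
})

test_that("LDA training accuracy is invariant under affine feature maps", {
  set.seed(13)
  X <- rbind(matrix(rnorm(40, 0, 1.5), 20, 2),
             matrix(rnorm(40, 3, 1.5), 20, 2),
             matrix(rnorm(40, 6, 1.5), 20, 2))
  y <- rep(0:2, each = 20)
  A <- matrix(c(2, 0.5, -1, 3), 2, 2)  # invertible
  acc1 <- mean(lda_fit(X, y, regularization = 0)$predicted == y)
  acc2 <- mean(lda_fit(X %*% A + 7, y, regularization = 0)$predicted == y)
  expect_equal(acc1, acc2)
})

test_that("LDA predictions agree with an established reference on clean data", {
  skip_if_not_installed("MASS")
  set.seed(14)
  X <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
             matrix(rnorm(60, 4, 1), 30, 2))
  y <- rep(0:1, each = 30)
  ours <- lda_fit(X, y, regularization = 0)$predicted
  ref <- as.integer(as.character(
    stats::predict(MASS::lda(X, grouping = y))$class))
  expect_gte(mean(ours == ref), 0.98)
})

test_that("singular scatter without regularization is diagnosed", {
  X <- cbind(x1 = rep(c(0, 10, 20), each = 4),
             x2 = rep(c(0, 10, 20), each = 4))  # collinear, zero within-var
  y <- rep(0:2, each = 4)
  expect_error(lda_fit(X, y, regularization = 0), "regulari[sz]ation")
  fit <- lda_fit(X, y, regularization = 1e-4)
  expect_equal(mean(fit$predicted == y), 1.0)
})

test_that("score correlation is high for separated classes, null under shuffling", {
  cl <- three_clusters(sd = 0.5)
  fit <- lda_fit(cl$X, cl$y)
  expect_gte(score_correlation(fit, cl$y), 0.95)

  # large-n permutation null so the in-sample fit bias (~ sqrt(k/n)) is small
  cl <- three_clusters(n = 40, sd = 0.5)
  null_r <- sapply(1:20, function(s) {
    set.seed(s)
    ys <- sample(cl$y)
    score_correlation(lda_fit(cl$X, ys), ys)
  })
  expect_lte(mean(abs(null_r)), 0.15)
  expect_error(score_correlation(fit, rep(1, nrow(fit$projections))),
               "constant")
})

test_that("combining a matrix with itself reproduces the single-matrix PCA", {
  set.seed(15)
  X <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(sprintf("s%02d", 1:30), sprintf("f%02d", 1:10)))
  single <- pca_project(X)
  both <- pca_project(cbind(a = X, b = X))
  expect_equal(single$explained_variance_ratio[1:9],
               both$explained_variance_ratio[1:9], tolerance = 1e-9)
  sc <- combine_tests(X, X, n_components = 3)
  expect_equal(ncol(sc), 3)
  expect_equal(nrow(sc), 30)
  expect_error(combine_tests(X, X[30:1, ]), "same subjects")
})

test_that("combining the two upper-limb tests preserves separation", {
  sil <- sapply(1:10, function(seed) {
    f <- lapply(c("FNT", "DDK"), function(tst) {
      ds <- simulate_cohort(c(10, 10, 10), tst, 50, seed = 100 + seed)
      band <- default_band(tst)
      pp <- preprocess_config(bandpass_low_hz = band[1],
                              bandpass_high_hz = band[2])
      features_from_dataset(ds, tst, pp, c(0.25, band[2]))
    })
    sev <- f[[1]]$severity
    alone <- vapply(f, function(fd) {
      pr <- pca_project(as_feature_matrix(fd))
      k <- choose_n_components(pr)
      silhouette_value(pr$scores[, seq_len(k), drop = FALSE], sev)
    }, numeric(1))
    comb <- combine_tests(as_feature_matrix(f[[1]]),
                          as_feature_matrix(f[[2]]), 3)
    c(min_alone = min(alone), combined = silhouette_value(comb, sev))
  })
  expect_gte(mean(sil["combined", ]) - mean(sil["min_alone", ]), -0.05)
})
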