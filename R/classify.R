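#' Standardised principal component projection
#'
#' Features are z-scored internally (RF in Hz and MR in spectrum units are
#' incommensurate) before the orthogonal transformation; explained-variance
#' ratios are reported over all components and sum to 1.
#'
#' @param X subjects x features numeric matrix.
#' @param n_components number of components to retain in `scores` and
#'   `loadings`; at most `min(nrow(X) - 1, ncol(X))`.
#' @return An object of class `pca_projection` with `scores`
#'   (subjects x n_components), `loadings` (features x n_components),
#'   `explained_variance_ratio` (all components), `n_components`,
#'   `feature_means`, `feature_scales`.
#' @export
pca_project <- function(X, n_components = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop("PCA needs at least 2 subjects", call. = FALSE)
  k_max <- min(n - 1, p)
  if (is.null(n_components)) n_components <- k_max
  if (n_components < 1 || n_components > k_max) {
    stop(sprintf("n_components must lie in [1, %d]", k_max), call. = FALSE)
  }
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- 1  # constant features carry no variance; leave centered
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = pc$x[, seq_len(n_components), drop = FALSE],
      loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
      explained_variance_ratio = evr,
      n_components = n_components,
      feature_means = mu,
      feature_scales = sds
    ),
    class = "pca_projection"
  )
}

# Project new observations into an existing PCA space.
pca_transform <- function(projection, X) {
  Z <- sweep(sweep(as.matrix(X), 2, projection$feature_means), 2,
             projection$feature_scales, "/")
  Z %*% projection$loadings
}

#' Smallest component count reaching a cumulative-variance threshold
#'
#' @param projection a [pca_projection()].
#' @param threshold cumulative explained-variance target (default 0.95).
#' @param cap upper bound on the count (default 3).
#' @return Integer component count.
#' @export
choose_n_components <- function(projection, threshold = 0.95, cap = 3) {
  cum <- cumsum(projection$explained_variance_ratio)
  k <- which(cum >= threshold)[1]
  if (is.na(k)) k <- length(cum)
  min(k, cap, length(cum))
}

#' Mean silhouette coefficient
#'
#' For each point, `a` is its mean Euclidean distance to the other members
#' of its own class and `b` the smallest mean distance to any other class;
#' the silhouette is `(b - a) / max(a, b)`, with singleton-class points
#' contributing 0. The returned value is the mean over all points.
#'
#' @param points subjects x dims numeric matrix.
#' @param labels per-subject class labels (>= 2 distinct values).
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_value <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.vector(labels)
  n <- nrow(points)
  stopifnot(n == length(labels))
  classes <- unique(labels)
  if (length(classes) < 2) {
    stop("silhouette undefined for a single class", call. = FALSE)
  }
  D <- as.matrix(stats::dist(points))
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) return(0)  # singleton convention
    a <- sum(D[i, own]) / n_own
    b <- min(vapply(classes[classes != labels[i]], function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Fisher linear discriminant severity model
#'
#' Solves the generalised eigenproblem of the between-class against the
#' (ridge-regularised) within-class scatter, retaining at most
#' `n_classes - 1` discriminants. The first discriminant is oriented so the
#' lowest class label (controls) has the highest mean, giving correlations
#' with clinical scores a stable sign. Prediction assigns the nearest class
#' mean in discriminant space.
#'
#' @param X subjects x features numeric matrix.
#' @param y per-subject class labels (e.g. severity 0/1/2), each class with
#'   >= 2 members.
#' @param regularization ridge weight lambda; `lambda * tr(Sw)/p * I` is
#'   added to the within-class scatter. Default 1e-4. With 0, a singular
#'   scatter is an error.
#' @return An object of class `lda_model` with `projections`, `predicted`,
#'   `class_stats` (per-class min/median/max/mean/range/IQR of the first
#'   discriminant), `scaling`, `class_means`, `classes`, `grand_mean`.
#' @export
lda_fit <- function(X, y, regularization = 1e-4) {
  X <- as.matrix(X)
  y <- as.vector(y)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(n == length(y))
  if (!all(is.finite(X))) stop("features must be finite", call. = FALSE)
  classes <- sort(unique(y))
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2)) {
    stop(sprintf("every class needs >= 2 subjects (class %s has %d)",
                 names(counts)[which.min(counts)], min(counts)),
         call. = FALSE)
  }
  grand <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  mus <- matrix(NA_real_, length(classes), p,
                dimnames = list(as.character(classes), colnames(X)))
  for (ci in seq_along(classes)) {
    idx <- y == classes[ci]
    mu_c <- colMeans(X[idx, , drop = FALSE])
    mus[ci, ] <- mu_c
    Xc <- sweep(X[idx, , drop = FALSE], 2, mu_c)
    Sw <- Sw + crossprod(Xc)
    d <- mu_c - grand
    Sb <- Sb + sum(idx) * tcrossprod(d)
  }
  if (regularization > 0) {
    tr <- sum(diag(Sw))
    Sw <- Sw + regularization * (if (tr > 0) tr / p else 1) * diag(p)
  }
  M <- tryCatch(
    solve(Sw, Sb),
    error = function(e) {
      stop("within-class scatter is singular; use regularization > 0",
           call. = FALSE)
    }
  )
  eg <- eigen(M)
  d <- min(length(classes) - 1, p)
  ord <- order(Re(eg$values), decreasing = TRUE)[seq_len(d)]
  W <- Re(eg$vectors[, ord, drop = FALSE])
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  proj <- sweep(X, 2, grand) %*% W
  mu_proj <- sweep(mus, 2, grand) %*% W
  # orient the first discriminant: controls (lowest class) highest
  if (mu_proj[1, 1] < mu_proj[nrow(mu_proj), 1]) {
    W[, 1] <- -W[, 1]
    proj[, 1] <- -proj[, 1]
    mu_proj[, 1] <- -mu_proj[, 1]
  }
  predict_from_proj <- function(pr) {
    idx <- apply(pr, 1, function(z) {
      which.min(colSums((t(mu_proj) - z)^2))
    })
    classes[idx]
  }
  predicted <- predict_from_proj(proj)
  class_stats <- lapply(seq_along(classes), function(ci) {
    v <- proj[y == classes[ci], 1]
    list(min = min(v), median = stats::median(v), max = max(v),
         mean = mean(v), range = max(v) - min(v),
         iqr = stats::IQR(v))
  })
  names(class_stats) <- as.character(classes)
  structure(
    list(projections = proj, predicted = predicted,
         class_stats = class_stats, scaling = W, class_means = mu_proj,
         classes = classes, grand_mean = grand),
    class = "lda_model"
  )
}

#' Project and classify new observations with a fitted discriminant model
#'
#' @param object an `lda_model` from [lda_fit()].
#' @param newdata observations x features matrix (same feature space).
#' @param ... unused.
#' @return List with `projections` and `predicted`.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  pr <- sweep(as.matrix(newdata), 2, object$grand_mean) %*% object$scaling
  idx <- apply(pr, 1, function(z) {
    which.min(colSums((t(object$class_means) - z)^2))
  })
  list(projections = pr, predicted = object$classes[idx])
}

#' Pearson correlation between discriminant score and clinical score
#'
#' Uses the negated first discriminant (which increases with severity under
#' the model's orientation convention) so the association is reported in
#' the positive direction.
#'
#' @param result an `lda_model` from [lda_fit()].
#' @param clinical_scores per-subject severity scores, aligned with the
#'   model's training rows.
#' @return Pearson correlation coefficient.
#' @export
score_correlation <- function(result, clinical_scores) {
  stopifnot(inherits(result, "lda_model"))
  scores <- as.numeric(clinical_scores)
  if (length(scores) != nrow(result$projections)) {
    stop("clinical scores are not aligned with the fitted subjects",
         call. = FALSE)
  }
  pearson_r(-result$projections[, 1], scores)
}

#' Combine two tests' feature matrices through PCA
#'
#' Column-concatenates the matrices (subjects must match and be in the same
#' order), standardises and projects, returning the leading component
#' scores — the upper-limb combination of the finger-to-nose and
#' alternating-movement tests.
#'
#' @param fv_test_a,fv_test_b subjects x features matrices with matching
#'   row names.
#' @param n_components number of leading component scores to return.
#' @return Subjects x n_components score matrix.
#' @export
combine_tests <- function(fv_test_a, fv_test_b, n_components = 3) {
  A <- as.matrix(fv_test_a)
  B <- as.matrix(fv_test_b)
  if (nrow(A) != nrow(B) ||
      (!is.null(rownames(A)) && !is.null(rownames(B)) &&
       !identical(rownames(A), rownames(B)))) {
    stop("the two matrices must cover the same subjects in the same order",
         call. = FALSE)
  }
  colnames(A) <- paste0("a.", colnames(A))
  colnames(B) <- paste0("b.", colnames(B))
  combined <- cbind(A, B)
  proj <- pca_project(combined,
                      min(n_components, nrow(combined) - 1, ncol(combined)))
  proj$scores
}

# The full per-fold severity chain: z-score+PCA (component count chosen by
# cumulative explained variance, capped) then Fisher LDA.
fit_severity_model <- function(X, y, variance_threshold = 0.95,
                               max_components = 3, regularization = 1e-4) {
  proj <- pca_project(X)
  k <- choose_n_components(proj, variance_threshold, max_components)
  lda <- lda_fit(proj$scores[, seq_len(k), drop = FALSE], y, regularization)
  structure(list(pca = proj, n_components = k, lda = lda),
            class = "severity_model")
}

#' @export
predict.severity_model <- function(object, newdata, ...) {
  sc <- pca_transform(object$pca, newdata)[, seq_len(object$n_components),
                                           drop = FALSE]
  predict(object$lda, sc)
}
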