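#' Stratified k-fold cross-validation of the severity classifier
#'
#' Folds are stratified by class with seeded shuffling; in each fold the
#' full chain (z-score, PCA with cumulative-variance component choice,
#' Fisher LDA) is refitted on the training split and applied to the held-out
#' split. Accuracy is three-class; sensitivity (TPR) and specificity are
#' defined at the patient-vs-control binarisation: a patient (class 1 or 2)
#' counts as correctly detected when predicted as any patient class, and a
#' control as correctly rejected when predicted control.
#'
#' @param X subjects x features numeric matrix.
#' @param y per-subject severity labels (0, 1, 2), each class >= 2 members.
#' @param k requested fold count (default 10); if it exceeds the smallest
#'   class count it is reduced to that count with a warning, recorded in
#'   the report.
#' @param seed RNG seed controlling the fold assignment.
#' @param variance_threshold,max_components,regularization passed to the
#'   per-fold PCA+LDA chain.
#' @return An object of class `cv_report`: `k_requested`, `k`, `seed`,
#'   `accuracy`, `sensitivity`, `specificity`, `tpr`, `fpr`, `error`,
#'   `per_fold`, `confusion` (3x3, rows = true class), `predicted`,
#'   `oof_score` (out-of-fold patient-direction discriminant score),
#'   `truth`.
#' @export
stratified_kfold_cv <- function(X, y, k = 10, seed = 1,
                                variance_threshold = 0.95,
                                max_components = 3,
                                regularization = 1e-4) {
  X <- as.matrix(X)
  y <- as.vector(y)
  n <- nrow(X)
  stopifnot(n == length(y))
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  classes <- sort(unique(y))
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2)) {
    stop("every class needs at least 2 subjects for stratified CV",
         call. = FALSE)
  }
  k_requested <- as.integer(k)
  min_count <- min(counts)
  if (k_requested > min_count) {
    warning(sprintf(
      "k = %d exceeds the smallest class count (%d); using k = %d",
      k_requested, min_count, min_count), call. = FALSE)
    k <- as.integer(min_count)
  } else {
    k <- k_requested
  }
  fold_of <- integer(n)
  fold_seeds <- derive_seeds(seed, length(classes))
  for (ci in seq_along(classes)) {
    idx <- which(y == classes[ci])
    idx <- with_seed(fold_seeds[ci], sample(idx))
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  predicted <- rep(NA_real_, n)
  oof_score <- rep(NA_real_, n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    model <- fit_severity_model(X[train_idx, , drop = FALSE], y[train_idx],
                                variance_threshold, max_components,
                                regularization)
    pr <- predict(model, X[test_idx, , drop = FALSE])
    predicted[test_idx] <- pr$predicted
    oof_score[test_idx] <- -pr$projections[, 1]  # patient direction
    per_fold[[f]] <- list(
      fold = f, n_test = length(test_idx),
      accuracy = mean(pr$predicted == y[test_idx])
    )
  }
  accuracy <- mean(predicted == y)
  is_pat <- y > 0
  pred_pat <- predicted > 0
  sensitivity <- if (any(is_pat)) mean(pred_pat[is_pat]) else NA_real_
  specificity <- if (any(!is_pat)) mean(!pred_pat[!is_pat]) else NA_real_
  confusion <- table(
    true = factor(y, levels = classes),
    predicted = factor(predicted, levels = classes)
  )
  structure(
    list(
      k_requested = k_requested, k = k, seed = seed,
      accuracy = accuracy, sensitivity = sensitivity,
      specificity = specificity, tpr = sensitivity,
      fpr = 1 - specificity, error = 1 - accuracy,
      per_fold = per_fold, confusion = unclass(confusion),
      predicted = predicted, oof_score = oof_score, truth = y
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> k = %d (seed %s): accuracy %.3f, TPR %.3f, FPR %.3f, error %.3f\n",
    x$k, format(x$seed), x$accuracy, x$tpr, x$fpr, x$error))
  invisible(x)
}

#' ROC curve and AUC for a patient-direction score
#'
#' Sweeps a threshold over the unique score values (a subject is called a
#' patient when its score is >= the threshold); tied scores step the curve
#' diagonally in one move. The AUC is the trapezoidal area under the
#' (FPR, TPR) curve and equals the Mann-Whitney U statistic divided by
#' `n1 * n0`.
#'
#' @param score per-subject real score, larger = more patient-like.
#' @param is_patient logical vector.
#' @return An object of class `roc_result` with `thresholds`, `tpr_curve`,
#'   `fpr_curve`, `auc`.
#' @export
roc_auc <- function(score, is_patient) {
  stopifnot(length(score) == length(is_patient))
  is_patient <- as.logical(is_patient)
  n1 <- sum(is_patient)
  n0 <- sum(!is_patient)
  if (n1 == 0 || n0 == 0) {
    stop("both patients and controls are required for a ROC curve",
         call. = FALSE)
  }
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(score >= t & is_patient) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & !is_patient) / n0,
                numeric(1))
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  thresholds <- c(Inf, thr)
  if (tpr[length(tpr)] < 1 || fpr[length(fpr)] < 1) {
    tpr <- c(tpr, 1)
    fpr <- c(fpr, 1)
    thresholds <- c(thresholds, -Inf)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(thresholds = thresholds, tpr_curve = tpr, fpr_curve = fpr,
         auc = auc),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}
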