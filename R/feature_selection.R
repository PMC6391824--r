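#' Patient-vs-control p-value for one feature
#'
#' Two-sided Welch (unequal-variance) two-sample t-test by default, with a
#' Mann-Whitney (Wilcoxon rank-sum) alternative. Degenerate inputs with
#' zero variance in both groups return p = 1 when the means agree.
#'
#' @param values numeric feature values, one per subject.
#' @param is_patient logical vector, `TRUE` for patients.
#' @param family `"welch"` or `"wilcoxon"`.
#' @return p-value in \[0, 1\].
#' @export
cohort_pvalue <- function(values, is_patient, family = c("welch", "wilcoxon")) {
  family <- match.arg(family)
  stopifnot(length(values) == length(is_patient))
  g1 <- values[is_patient]
  g0 <- values[!is_patient]
  if (length(g1) < 2 || length(g0) < 2) {
    stop("each cohort needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(g1) == 0 && stats::sd(g0) == 0) {
    return(if (mean(g1) == mean(g0)) 1.0 else 0.0)
  }
  if (family == "wilcoxon") {
    return(suppressWarnings(
      stats::wilcox.test(g1, g0, exact = FALSE)$p.value))
  }
  tryCatch(
    stats::t.test(g1, g0, var.equal = FALSE)$p.value,
    error = function(e) if (mean(g1) == mean(g0)) 1.0 else 0.0
  )
}

#' Pearson product-moment correlation
#'
#' [stats::cor()] wrapped with the error contract used throughout the
#' pipeline: equal lengths of at least 3 and non-constant inputs.
#'
#' @param x,y numeric sequences.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations",
                          call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Univariate feature selection with correlation reporting
#'
#' Implements the selection rule used throughout the pipeline: a feature is
#' kept when its patient-vs-control p-value is below `alpha` (raw, no
#' multiple-testing correction by default, with an optional
#' Benjamini-Hochberg switch), and additionally flagged *strong* when the
#' absolute Pearson correlation with the clinical severity score reaches
#' `r_min`. Correlations are reported for every feature, kept or not.
#'
#' @param feature_matrix numeric subjects x features matrix (named columns)
#'   or a [features_from_dataset()] data frame.
#' @param is_patient logical per-subject labels (`TRUE` = patient). Defaults
#'   to `clinical_scores > 0`.
#' @param clinical_scores per-subject severity scores (0, 1, 2).
#' @param alpha significance threshold (default 0.05).
#' @param r_min absolute-correlation threshold for the strong flag
#'   (default 0.5).
#' @param family test family passed to [cohort_pvalue()].
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg.
#' @return An object of class `selected_features` with fields `kept`
#'   (character, ordered by canonical name), `p_values`, `correlations`,
#'   `strong`, `alpha`, `r_min`.
#' @export
select_features <- function(feature_matrix, clinical_scores,
                            is_patient = clinical_scores > 0,
                            alpha = 0.05, r_min = 0.5,
                            family = c("welch", "wilcoxon"),
                            adjust = c("none", "BH")) {
  family <- match.arg(family)
  adjust <- match.arg(adjust)
  if (is.data.frame(feature_matrix) && "subject_id" %in% names(feature_matrix)) {
    feature_matrix <- as_feature_matrix(feature_matrix)
  }
  X <- as.matrix(feature_matrix)
  if (is.null(colnames(X))) stop("feature matrix must have named columns",
                                 call. = FALSE)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]",
                                       call. = FALSE)
  if (r_min < 0 || r_min > 1) stop("r_min must lie in [0, 1]", call. = FALSE)
  stopifnot(nrow(X) == length(clinical_scores),
            nrow(X) == length(is_patient))
  if (sum(is_patient) < 2 || sum(!is_patient) < 2) {
    stop("each cohort needs at least 2 subjects", call. = FALSE)
  }
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  nm <- sort(colnames(X))
  X <- X[, nm, drop = FALSE]
  p <- vapply(nm, function(f) cohort_pvalue(X[, f], is_patient, family),
              numeric(1))
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  r <- vapply(nm, function(f) {
    tryCatch(pearson_r(X[, f], as.numeric(clinical_scores)),
             error = function(e) NA_real_)
  }, numeric(1))
  kept <- nm[p < alpha]
  strong <- !is.na(r) & abs(r) >= r_min
  structure(
    list(kept = kept, p_values = p, correlations = r, strong = strong,
         alpha = alpha, r_min = r_min, family = family, adjust = adjust),
    class = "selected_features"
  )
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf(
    "<selected_features> %d of %d features kept at p < %g (%s test); %d strong (|r| >= %g)\n",
    length(x$kept), length(x$p_values), x$alpha, x$family,
    sum(x$strong), x$r_min))
  invisible(x)
}
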