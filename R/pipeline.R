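#' Default band-pass edges per test
#'
#' The alternating-movement (DDK) test uses the 2-5 Hz band; the
#' finger-to-nose and heel-to-shin movements are slower, so their default
#' bands extend down to 0.5 and 0.3 Hz so the movement fundamental lies in
#' the passband. A band upper edge at or above Nyquist is clamped to
#' 0.99 x Nyquist.
#'
#' @param test `"FNT"`, `"DDK"` or `"HST"`.
#' @return Numeric pair `(low, high)` in Hz.
#' @export
default_band <- function(test) {
  switch(match.arg(test, TESTS),
         FNT = c(0.5, 5), DDK = c(2, 5), HST = c(0.3, 5))
}

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `manifest` (a dataset manifest CSV) or `synthesis` (a
#' list with `n_per_class`, `seed`, and optionally `subject_sd`) must be
#' given.
#'
#' @param manifest path to a manifest CSV, or `NULL`.
#' @param synthesis synthetic-cohort spec, or `NULL`.
#' @param tests character vector of tests to analyse.
#' @param sampling_rate_hz sampling rate (Hz).
#' @param band band-pass edges per test: `NULL` for [default_band()], a
#'   numeric pair applied to all tests, or a named list per test.
#' @param lowpass,filter_order low-pass cutoff (Hz) and filter order.
#' @param alpha,r_min,test_family feature-selection settings.
#' @param variance_threshold,max_components,regularization classifier
#'   settings.
#' @param k,cv_seed cross-validation settings.
#' @param combine optional pair of tests to combine through PCA.
#' @param out_dir output directory for report files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, synthesis = NULL,
                            tests = "DDK", sampling_rate_hz = 50,
                            band = NULL, lowpass = 10, filter_order = 6,
                            alpha = 0.05, r_min = 0.5,
                            test_family = "welch",
                            variance_threshold = 0.95, max_components = 3,
                            regularization = 1e-4,
                            k = 10, cv_seed = 1,
                            combine = NULL, out_dir = ".") {
  if (is.null(manifest) == is.null(synthesis)) {
    stop("exactly one of 'manifest' or 'synthesis' must be given",
         call. = FALSE)
  }
  tests <- vapply(tests, match.arg, character(1), TESTS)
  names(tests) <- NULL
  if (!is.null(synthesis)) {
    if (!is.list(synthesis) || is.null(synthesis$n_per_class) ||
        is.null(synthesis$seed)) {
      stop("synthesis spec needs 'n_per_class' and 'seed'", call. = FALSE)
    }
    if (length(synthesis$n_per_class) != 3) {
      stop("synthesis n_per_class must have 3 entries", call. = FALSE)
    }
    if (is.null(synthesis$subject_sd)) synthesis$subject_sd <- 0.06
  }
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha <= 1)) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (!(r_min >= 0 && r_min <= 1)) stop("r_min must lie in [0, 1]",
                                        call. = FALSE)
  test_family <- match.arg(test_family, c("welch", "wilcoxon"))
  if (k < 2) stop("cv k must be at least 2", call. = FALSE)
  if (regularization < 0) stop("regularization must be >= 0", call. = FALSE)
  nyq <- sampling_rate_hz / 2
  band_for <- function(tst) {
    b <- if (is.null(band)) {
      default_band(tst)
    } else if (is.list(band)) {
      if (is.null(band[[tst]])) default_band(tst) else as.numeric(band[[tst]])
    } else {
      as.numeric(band)
    }
    if (b[2] >= nyq) b[2] <- 0.99 * nyq
    if (!(b[1] > 0 && b[1] < b[2])) {
      stop(sprintf("invalid band for %s: [%g, %g]", tst, b[1], b[2]),
           call. = FALSE)
    }
    b
  }
  bands <- lapply(stats::setNames(tests, tests), band_for)
  if (!is.null(combine)) {
    combine <- vapply(combine, match.arg, character(1), TESTS)
    names(combine) <- NULL
    if (length(combine) != 2 || !all(combine %in% tests)) {
      stop("'combine' must name two tests included in 'tests'",
           call. = FALSE)
    }
  }
  structure(
    list(manifest = manifest, synthesis = synthesis, tests = tests,
         sampling_rate_hz = sampling_rate_hz, bands = bands,
         lowpass = lowpass, filter_order = filter_order,
         alpha = alpha, r_min = r_min, test_family = test_family,
         variance_threshold = variance_threshold,
         max_components = max_components,
         regularization = regularization, k = k, cv_seed = cv_seed,
         combine = combine, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path),
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the full assessment pipeline
#'
#' Loads or synthesises the dataset, then per test: extracts the 60-feature
#' matrix, runs feature selection, PCA + silhouette separation, the LDA
#' severity model with its clinical-score correlation, stratified k-fold
#' cross-validation and ROC/AUC. Writes, per test, `features_<test>.csv`,
#' `selection_<test>.json`, `classification_<test>.json`, `cv_<test>.json`
#' and `roc_<test>.csv`, plus `classification_combined.json` when a test
#' combination is configured and a deterministic `run_log.txt`.
#'
#' @param config a [pipeline_config()] or path to a config file.
#' @return Invisibly, a named list of the per-test result objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("ataximu pipeline, package version %s",
            as.character(utils::packageVersion("ataximu"))),
    sprintf("cv seed: %s", format(config$cv_seed)),
    if (!is.null(config$synthesis)) {
      sprintf("synthesis: n_per_class = %s, seed = %s, subject_sd = %g",
              paste(config$synthesis$n_per_class, collapse = "/"),
              format(config$synthesis$seed), config$synthesis$subject_sd)
    } else {
      sprintf("manifest: %s", config$manifest)
    }
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  results <- list()
  matrices <- list()
  for (tst in config$tests) {
    dataset <- stage(paste0("input/", tst), {
      if (!is.null(config$manifest)) {
        load_dataset(config$manifest, config$sampling_rate_hz)
      } else {
        simulate_cohort(config$synthesis$n_per_class, tst,
                        config$sampling_rate_hz, config$synthesis$seed,
                        subject_sd = config$synthesis$subject_sd)
      }
    })
    band <- config$bands[[tst]]
    pp <- preprocess_config(
      lowpass_cutoff_hz = config$lowpass,
      bandpass_low_hz = band[1], bandpass_high_hz = band[2],
      bandpass_order = config$filter_order,
      lowpass_order = config$filter_order
    )
    rf_band <- c(0.25, band[2])
    feats <- stage(paste0("features/", tst), {
      features_from_dataset(dataset, tst, pp, rf_band)
    })
    utils::write.csv(feats,
                     file.path(config$out_dir,
                               sprintf("features_%s.csv", tst)),
                     row.names = FALSE)
    X <- as_feature_matrix(feats)
    sev <- feats$severity
    sel <- stage(paste0("selection/", tst), {
      select_features(X, clinical_scores = sev, alpha = config$alpha,
                      r_min = config$r_min, family = config$test_family)
    })
    write_report_json(
      list(test = tst, alpha = sel$alpha, r_min = sel$r_min,
           family = sel$family, kept = sel$kept,
           features = lapply(stats::setNames(names(sel$p_values),
                                             names(sel$p_values)),
                             function(f) list(
                               p = sel$p_values[[f]],
                               r = sel$correlations[[f]],
                               kept = f %in% sel$kept,
                               strong = unname(sel$strong[f])))),
      file.path(config$out_dir, sprintf("selection_%s.json", tst)))
    cls <- stage(paste0("classify/", tst), {
      proj <- pca_project(X)
      n_pcs <- choose_n_components(proj, config$variance_threshold,
                                   config$max_components)
      scores <- proj$scores[, seq_len(n_pcs), drop = FALSE]
      sil <- silhouette_value(scores, sev)
      lda <- lda_fit(scores, sev, config$regularization)
      list(projection = proj, n_pcs = n_pcs, silhouette = sil,
           lda = lda, correlation = score_correlation(lda, sev))
    })
    write_report_json(
      list(test = tst, n_components = cls$n_pcs,
           explained_variance_ratio =
             cls$projection$explained_variance_ratio[seq_len(cls$n_pcs)],
           silhouette = cls$silhouette,
           correlation = cls$correlation,
           class_stats = cls$lda$class_stats,
           predicted = cls$lda$predicted),
      file.path(config$out_dir, sprintf("classification_%s.json", tst)))
    cv <- stage(paste0("cv/", tst), {
      stratified_kfold_cv(X, sev, k = config$k, seed = config$cv_seed,
                          variance_threshold = config$variance_threshold,
                          max_components = config$max_components,
                          regularization = config$regularization)
    })
    write_report_json(
      list(test = tst, k_requested = cv$k_requested, k = cv$k,
           seed = cv$seed, accuracy = cv$accuracy,
           sensitivity = cv$sensitivity, specificity = cv$specificity,
           tpr = cv$tpr, fpr = cv$fpr, error = cv$error,
           confusion = cv$confusion, per_fold = cv$per_fold),
      file.path(config$out_dir, sprintf("cv_%s.json", tst)))
    roc <- stage(paste0("roc/", tst), {
      roc_auc(cv$oof_score, sev > 0)
    })
    utils::write.csv(
      data.frame(fpr = roc$fpr_curve, tpr = roc$tpr_curve,
                 threshold = roc$thresholds),
      file.path(config$out_dir, sprintf("roc_%s.csv", tst)),
      row.names = FALSE)
    log_lines <- c(log_lines, sprintf(
      "%s: band [%g, %g] Hz, %d/60 features kept, silhouette %.4f, r %.4f, CV accuracy %.4f, AUC %.4f",
      tst, band[1], band[2], length(sel$kept), cls$silhouette,
      cls$correlation, cv$accuracy, roc$auc))
    results[[tst]] <- list(features = feats, selection = sel,
                           classification = cls, cv = cv, roc = roc)
    matrices[[tst]] <- X
  }
  if (!is.null(config$combine)) {
    comb <- stage("combine", {
      a <- config$combine[1]
      b <- config$combine[2]
      sev <- results[[a]]$features$severity
      scores <- combine_tests(matrices[[a]], matrices[[b]],
                              config$max_components)
      sil <- silhouette_value(scores, sev)
      lda <- lda_fit(scores, sev, config$regularization)
      list(tests = config$combine, silhouette = sil, lda = lda,
           correlation = score_correlation(lda, sev))
    })
    write_report_json(
      list(tests = comb$tests, silhouette = comb$silhouette,
           correlation = comb$correlation,
           class_stats = comb$lda$class_stats),
      file.path(config$out_dir, "classification_combined.json"))
    log_lines <- c(log_lines, sprintf(
      "combined %s+%s: silhouette %.4f, r %.4f",
      comb$tests[1], comb$tests[2], comb$silhouette, comb$correlation))
    results$combined <- comb
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(results)
}
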