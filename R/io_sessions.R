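#' Construct an IMU recording
#'
#' An `imu_recording` holds uniformly sampled tri-axial accelerometer and
#' gyroscope channels from a wearable inertial sensor. Channels are stored
#' as a six-column numeric matrix (`ax, ay, az, gx, gy, gz`); timestamps are
#' implicit from the sampling rate (uniform sampling is assumed).
#'
#' @param accel numeric matrix or data frame with columns X, Y, Z (m/s^2).
#' @param gyro numeric matrix or data frame with columns X, Y, Z (deg/s).
#' @param sampling_rate_hz positive sampling rate in Hz.
#' @return An object of class `imu_recording` with elements `accel` (n x 3),
#'   `gyro` (n x 3), `sampling_rate_hz`, `n_samples`.
#' @export
imu_recording <- function(accel, gyro, sampling_rate_hz) {
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a single positive number", call. = FALSE)
  }
  if (ncol(accel) != 3 || ncol(gyro) != 3) {
    stop("accel and gyro must each have 3 columns (X, Y, Z)", call. = FALSE)
  }
  if (nrow(accel) != nrow(gyro)) {
    stop("accelerometer and gyroscope channels must have equal length", call. = FALSE)
  }
  if (nrow(accel) < 1) {
    stop("recording must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(accel)) || !all(is.finite(gyro))) {
    stop("recording contains non-finite values", call. = FALSE)
  }
  colnames(accel) <- c("X", "Y", "Z")
  colnames(gyro) <- c("X", "Y", "Z")
  structure(
    list(
      accel = accel,
      gyro = gyro,
      sampling_rate_hz = sampling_rate_hz,
      n_samples = nrow(accel)
    ),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> %d samples @ %g Hz (%.1f s)\n",
    x$n_samples, x$sampling_rate_hz, x$n_samples / x$sampling_rate_hz
  ))
  invisible(x)
}

REC_COLUMNS <- c("ax", "ay", "az", "gx", "gy", "gz")
TESTS <- c("FNT", "DDK", "HST")
LIMBS <- c("L", "R")

#' Read an IMU recording from CSV
#'
#' The file must be a headered CSV with columns `ax, ay, az, gx, gy, gz`
#' (accelerometer in m/s^2, gyroscope in deg/s) and at least two data rows.
#'
#' @param path path to the CSV file.
#' @param sampling_rate_hz sampling rate of the recording in Hz.
#' @return An [imu_recording()].
#' @export
read_recording <- function(path, sampling_rate_hz) {
  if (!file.exists(path)) {
    stop(sprintf("recording file not found: '%s'", path), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA,
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(REC_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("recording '%s' is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) < 2) {
    stop(sprintf("recording '%s' has fewer than 2 data rows", path),
         call. = FALSE)
  }
  df <- df[REC_COLUMNS]
  for (col in REC_COLUMNS) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(num))
    if (length(bad) > 0) {
      # 1-based data line: +1 for header
      stop(sprintf("non-numeric value '%s' in column '%s' of '%s' at line %d",
                   as.character(v[bad[1]]), col, path, bad[1] + 1L),
           call. = FALSE)
    }
    df[[col]] <- num
  }
  imu_recording(
    accel = as.matrix(df[, c("ax", "ay", "az")]),
    gyro = as.matrix(df[, c("gx", "gy", "gz")]),
    sampling_rate_hz = sampling_rate_hz
  )
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_recording()]: the round trip reproduces every sample to
#' within 1e-9.
#'
#' @param recording an [imu_recording()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "imu_recording"))
  if (recording$n_samples < 2) {
    stop("refusing to write a recording with fewer than 2 samples",
         call. = FALSE)
  }
  df <- data.frame(
    ax = recording$accel[, "X"], ay = recording$accel[, "Y"],
    az = recording$accel[, "Z"],
    gx = recording$gyro[, "X"], gy = recording$gyro[, "Y"],
    gz = recording$gyro[, "Z"]
  )
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE), path, row.names = FALSE,
                     quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) {
    stop(sprintf("could not write recording to '%s'", path), call. = FALSE)
  }
  invisible(path)
}

#' Construct a labelled test session
#'
#' One subject x test x limb recording with its clinical metadata. Severity
#' follows the three-class convention: 0 = control, 1 = mild ataxia,
#' 2 = significant ataxia.
#'
#' @param subject_id subject identifier (character scalar).
#' @param test one of `"FNT"`, `"DDK"`, `"HST"`.
#' @param limb `"L"` or `"R"`.
#' @param severity integer 0, 1 or 2.
#' @param recording an [imu_recording()].
#' @return An object of class `test_session`.
#' @export
test_session <- function(subject_id, test, limb, severity, recording) {
  test <- as.character(test)
  limb <- as.character(limb)
  if (!test %in% TESTS) {
    stop(sprintf("unknown test '%s' (expected FNT, DDK or HST)", test),
         call. = FALSE)
  }
  if (!limb %in% LIMBS) {
    stop(sprintf("unknown limb '%s' (expected L or R)", limb), call. = FALSE)
  }
  sev <- suppressWarnings(as.integer(severity))
  if (is.na(sev) || !sev %in% 0:2) {
    stop(sprintf("severity must be 0, 1 or 2 (got '%s')",
                 as.character(severity)), call. = FALSE)
  }
  stopifnot(inherits(recording, "imu_recording"))
  structure(
    list(subject_id = as.character(subject_id), test = test, limb = limb,
         severity = sev, recording = recording),
    class = "test_session"
  )
}

#' Construct a dataset of test sessions
#'
#' Validates that no (subject, test, limb) triple is duplicated and that a
#' subject's severity label is consistent across all of their sessions.
#'
#' @param sessions list of [test_session()] objects.
#' @return An object of class `ataxia_dataset`.
#' @export
ataxia_dataset <- function(sessions) {
  stopifnot(is.list(sessions), all(vapply(sessions, inherits, logical(1),
                                          "test_session")))
  key <- vapply(sessions, function(s) {
    paste(s$subject_id, s$test, s$limb, sep = "|")
  }, character(1))
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (subject, test, limb) session: %s",
                 key[duplicated(key)][1]), call. = FALSE)
  }
  sev_by_subj <- split(
    vapply(sessions, `[[`, integer(1), "severity"),
    vapply(sessions, `[[`, character(1), "subject_id")
  )
  bad <- names(sev_by_subj)[vapply(sev_by_subj,
                                   function(v) length(unique(v)) > 1,
                                   logical(1))]
  if (length(bad) > 0) {
    stop(sprintf("inconsistent severity labels for subject(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(list(sessions = sessions), class = "ataxia_dataset")
}

#' @export
print.ataxia_dataset <- function(x, ...) {
  sev <- vapply(x$sessions, `[[`, integer(1), "severity")
  subj <- vapply(x$sessions, `[[`, character(1), "subject_id")
  cat(sprintf("<ataxia_dataset> %d sessions, %d subjects\n",
              length(x$sessions), length(unique(subj))))
  cat("  severity counts (sessions):",
      paste(sprintf("%d:%d", 0:2, tabulate(factor(sev, 0:2), 3)),
            collapse = " "), "\n")
  invisible(x)
}

#' Group a dataset's sessions into complete left/right pairs
#'
#' Feature extraction works on (subject, test) groups containing exactly one
#' left and one right session; this accessor returns those pairs.
#'
#' @param dataset an [ataxia_dataset()].
#' @param test optional test to restrict to.
#' @return A list of lists with elements `subject_id`, `test`, `severity`,
#'   `L`, `R` (the two sessions).
#' @export
session_pairs <- function(dataset, test = NULL) {
  stopifnot(inherits(dataset, "ataxia_dataset"))
  sessions <- dataset$sessions
  if (!is.null(test)) {
    test <- match.arg(test, TESTS)
    sessions <- Filter(function(s) s$test == test, sessions)
  }
  key <- vapply(sessions, function(s) paste(s$subject_id, s$test, sep = "|"),
                character(1))
  groups <- split(sessions, key)
  pairs <- lapply(groups, function(g) {
    limbs <- vapply(g, `[[`, character(1), "limb")
    if (length(g) != 2 || !setequal(limbs, LIMBS)) {
      stop(sprintf(
        "subject '%s' test '%s': expected exactly one L and one R session",
        g[[1]]$subject_id, g[[1]]$test), call. = FALSE)
    }
    list(subject_id = g[[1]]$subject_id, test = g[[1]]$test,
         severity = g[[1]]$severity,
         L = g[[which(limbs == "L")]], R = g[[which(limbs == "R")]])
  })
  names(pairs) <- NULL
  ord <- order(vapply(pairs, `[[`, character(1), "subject_id"))
  pairs[ord]
}

#' Load a labelled dataset from a manifest
#'
#' The manifest is a CSV with columns `subject_id, test, limb, severity,
#' path`; each `path` (relative paths are resolved against the manifest's
#' directory) points to a recording CSV readable by [read_recording()].
#'
#' @param manifest_path path to the manifest CSV.
#' @param sampling_rate_hz sampling rate shared by all recordings (Hz).
#' @return An [ataxia_dataset()].
#' @export
load_dataset <- function(manifest_path, sampling_rate_hz = 50) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: '%s'", manifest_path), call. = FALSE)
  }
  mf <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "test", "limb", "severity", "path")
  missing_cols <- setdiff(needed, names(mf))
  if (length(missing_cols) > 0) {
    stop(sprintf("manifest is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  base_dir <- dirname(manifest_path)
  sessions <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    sev <- suppressWarnings(as.integer(mf$severity[i]))
    if (is.na(sev) || !sev %in% 0:2) {
      stop(sprintf("manifest row %d: severity must be 0, 1 or 2 (got '%s')",
                   i, as.character(mf$severity[i])), call. = FALSE)
    }
    p <- mf$path[i]
    if (!file.exists(p)) {
      p2 <- file.path(base_dir, p)
      if (file.exists(p2)) p <- p2 else {
        stop(sprintf("manifest row %d: recording file not found: '%s'",
                     i, mf$path[i]), call. = FALSE)
      }
    }
    sessions[[i]] <- test_session(
      subject_id = mf$subject_id[i], test = mf$test[i], limb = mf$limb[i],
      severity = sev, recording = read_recording(p, sampling_rate_hz)
    )
  }
  ataxia_dataset(sessions)
}

#' Write a dataset to a directory of recording CSVs plus a manifest
#'
#' @param dataset an [ataxia_dataset()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ataxia_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$sessions, function(s) {
    fname <- sprintf("%s_%s_%s.csv", s$subject_id, s$test, s$limb)
    write_recording(s$recording, file.path(dir, fname))
    data.frame(subject_id = s$subject_id, test = s$test, limb = s$limb,
               severity = s$severity, path = fname,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
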