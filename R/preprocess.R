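# Preprocessing chain: direct decimation (no anti-aliasing, matching the
# use of pre-denoised signals), centered 512-sample windows, clinical
# discretization of metadata, one-hot encoding, record-level splits.

#' Metadata feature names in canonical one-hot order
#' @export
METADATA_FEATURES <- c("RAxis", "TAxis", "QRSDuration", "VentricularRate",
                       "QRSCount")

METADATA_LEVELS <- list(
  RAxis = c("Normal", "Left", "Right", "Extreme"),
  TAxis = c("Normal", "Left", "Right", "Extreme"),
  QRSDuration = c("Normal", "Prolonged"),
  VentricularRate = c("Bradycardia", "Normal", "Tachycardia"),
  QRSCount = c("Low", "Normal", "High"))

#' Direct decimation (every k-th sample, no filtering)
#'
#' @param x numeric vector, or a matrix whose columns are time samples.
#' @param factor positive integer decimation factor; the output keeps
#'   samples `0, factor, 2*factor, ...` (0-based), so a 5000-sample 500-Hz
#'   record at factor 5 yields exactly 1000 samples at 100 Hz.
#' @return The decimated vector/matrix.
#' @export
decimate <- function(x, factor) {
  if (length(factor) != 1 || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (is.matrix(x)) {
    if (ncol(x) < factor) stop("signal shorter than decimation factor")
    return(x[, seq(1L, ncol(x), by = factor), drop = FALSE])
  }
  if (length(x) < factor) stop("signal shorter than decimation factor")
  x[seq(1L, length(x), by = factor)]
}

#' Extract a centered fixed-length window
#'
#' The 0-based start index is `floor((T - length) / 2)`; the same start is
#' used for every lead of a record (pass the full lead matrix).
#'
#' @param x numeric vector, or a matrix whose columns are time samples.
#' @param length window length in samples (default 512).
#' @return The windowed vector/matrix.
#' @export
extract_window <- function(x, length = 512L) {
  n <- if (is.matrix(x)) ncol(x) else base::length(x)
  if (n < length) stop("signal shorter than the requested window")
  start <- (n - length) %/% 2L
  idx <- start + seq_len(length)
  if (is.matrix(x)) x[, idx, drop = FALSE] else x[idx]
}

.axis_category <- function(theta) {
  if (!is.finite(theta) || theta <= -180 || theta > 180)
    stop("axis angle must lie in (-180, 180]")
  if (theta >= -30 && theta <= 90) "Normal"
  else if (theta > -90 && theta < -30) "Left"
  else if (theta > 90 && theta <= 180) "Right"
  else "Extreme"
}

#' Discretize raw metadata into clinical categories
#'
#' Thresholds follow standard ECG interpretation criteria: axes are Normal
#' in \[-30, 90\] deg, Left in (-90, -30), Right in (90, 180\], Extreme in
#' (-180, -90\]; QRS duration is Prolonged at >= 120 ms; ventricular rate is
#' Bradycardia below 60 bpm, Normal in 60-100 (inclusive), Tachycardia above
#' 100; QRS count (per 10 s) is Low below 10, Normal in 10-16 (inclusive),
#' High at >= 17.
#'
#' @param raw named list with `RAxis`, `TAxis` (degrees), `VentricularRate`
#'   (bpm), `QRSCount` (per 10 s), `QRSDuration` (ms).
#' @return An object of class `metadata_categories`: a named character
#'   vector with one category per feature.
#' @export
discretize_metadata <- function(raw) {
  need <- METADATA_FEATURES
  if (!all(need %in% names(raw)))
    stop("raw metadata must contain: ", paste(need, collapse = ", "))
  vals <- lapply(raw[need], as.numeric)
  if (any(!vapply(vals[c("VentricularRate", "QRSCount", "QRSDuration")],
                  function(v) is.finite(v) && v >= 0, logical(1))))
    stop("rate, count and duration must be finite and >= 0")
  cats <- c(
    RAxis = .axis_category(vals$RAxis),
    TAxis = .axis_category(vals$TAxis),
    QRSDuration = if (vals$QRSDuration >= 120) "Prolonged" else "Normal",
    VentricularRate = if (vals$VentricularRate < 60) "Bradycardia"
                      else if (vals$VentricularRate <= 100) "Normal"
                      else "Tachycardia",
    QRSCount = if (vals$QRSCount < 10) "Low"
               else if (vals$QRSCount <= 16) "Normal"
               else "High")
  structure(cats, class = "metadata_categories")
}

#' One-hot encode discretized metadata
#'
#' Features are concatenated in the fixed order RAxis, TAxis, QRSDuration,
#' VentricularRate, QRSCount, each with its categories in the documented
#' listing order, giving D = 16 for the full set (4 + 4 + 2 + 3 + 3).
#'
#' @param cats a [discretize_metadata()] result.
#' @param features non-empty character subset of the five feature names;
#'   supports the single-feature / pairwise / full input configurations.
#' @return Named binary vector with exactly one 1 per selected feature.
#' @export
one_hot_metadata <- function(cats, features = METADATA_FEATURES) {
  if (length(features) == 0) stop("feature selection must be non-empty")
  features <- match.arg(features, METADATA_FEATURES, several.ok = TRUE)
  features <- METADATA_FEATURES[METADATA_FEATURES %in% features]
  out <- numeric(0)
  for (f in features) {
    lev <- METADATA_LEVELS[[f]]
    v <- as.numeric(lev == cats[[f]])
    names(v) <- paste(f, lev, sep = ".")
    out <- c(out, v)
  }
  out
}

#' Total one-hot dimension for a feature subset
#' @param features character subset of the five feature names.
#' @return Integer dimension D.
#' @export
one_hot_dim <- function(features = METADATA_FEATURES) {
  if (length(features) == 0) return(0L)
  features <- match.arg(features, METADATA_FEATURES, several.ok = TRUE)
  sum(vapply(METADATA_LEVELS[features], length, integer(1)))
}

#' Estimate raw metadata from a Lead I strip
#'
#' R peaks are detected with [detect_r_peaks()]; the QRS count is scaled to
#' a 10-s equivalent and the ventricular rate is `6 * QRSCount`.  QRS
#' duration is the mean width of the rectified QRS envelope above
#' `qrs_frac` of each R amplitude.  Frontal axes cannot be derived from a
#' single lead and are returned as `NA`.
#'
#' @param lead1 numeric vector (mV).
#' @param fs sampling rate in Hz.
#' @param qrs_frac envelope threshold as a fraction of the R amplitude.
#' @return Named list (`RAxis`, `TAxis` are `NA`).
#' @export
estimate_metadata_from_lead1 <- function(lead1, fs, qrs_frac = 0.25) {
  if (length(lead1) < 2 * fs) stop("need at least 2 s of signal")
  peaks <- suppressWarnings(detect_r_peaks(lead1, fs))
  if (length(peaks) == 0) stop("no QRS complexes detected (quality error)")
  dur_s <- length(lead1) / fs
  qrs_count <- round(length(peaks) * 10 / dur_s)
  env <- abs(lead1 - stats::median(lead1))
  widths <- vapply(peaks, function(p) {
    thr <- qrs_frac * env[p]
    i0 <- p; while (i0 > 1 && env[i0 - 1] > thr) i0 <- i0 - 1L
    i1 <- p; while (i1 < length(env) && env[i1 + 1] > thr) i1 <- i1 + 1L
    (i1 - i0 + 1L) / fs * 1000
  }, numeric(1))
  list(RAxis = NA_real_, TAxis = NA_real_,
       VentricularRate = 6 * qrs_count, QRSCount = qrs_count,
       QRSDuration = mean(widths))
}

#' Record-level train/validation/test split
#'
#' Sizes are `floor(n * fraction)` for train and validation with the
#' remainder assigned to test; assignment is a seeded permutation.
#'
#' @param n number of records (or a list of records).
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed integer seed (required).
#' @return Factor of length n with levels `train`, `val`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), seed) {
  if (is.list(n)) n <- length(n)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n_train <- floor(n * fractions[1])
  n_val <- floor(n * fractions[2])
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1)
    stop("n too small for non-empty splits")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  out <- character(n)
  out[perm[seq_len(n_train)]] <- "train"
  out[perm[n_train + seq_len(n_val)]] <- "val"
  out[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  factor(out, levels = c("train", "val", "test"))
}

#' Build model-ready windowed input/target pairs
#'
#' Each record is decimated to 100 Hz (direct decimation), a centered
#' 512-sample window is cut jointly across all 12 leads, Lead I becomes the
#' input and the remaining 11 leads (order II, III, aVR, aVL, aVF, V1-V6)
#' the target; metadata are discretized and one-hot encoded for the
#' selected feature subset.
#'
#' @param records list of [ecg_record()]s.
#' @param split optional factor from [split_dataset()] (recycled onto the
#'   `split` field of the result).
#' @param features metadata feature subset (character, possibly empty for
#'   the time-series-only configuration).
#' @param target_fs target sampling rate after decimation (Hz).
#' @param window window length in samples.
#' @return An object of class `windowed_pairs`: list with `X` (n x window
#'   Lead I matrix), `Y` (n x 11 x window target array), `M` (n x D one-hot
#'   matrix), `ids`, `split`, `features`, `fs`.
#' @export
make_windowed_pairs <- function(records, split = NULL,
                                features = METADATA_FEATURES,
                                target_fs = 100, window = 512L) {
  n <- length(records)
  D <- if (length(features)) one_hot_dim(features) else 0L
  X <- matrix(0, n, window)
  Y <- array(0, c(n, 11L, window))
  M <- matrix(0, n, max(D, 1L))[, seq_len(D), drop = FALSE]
  ids <- character(n)
  for (i in seq_len(n)) {
    r <- records[[i]]
    fac <- r$fs / target_fs
    if (fac != round(fac)) stop("fs must be an integer multiple of target_fs")
    sig <- if (fac > 1) decimate(r$signal, fac) else r$signal
    sig <- extract_window(sig, window)
    X[i, ] <- sig["I", ]
    Y[i, , ] <- sig[TARGET_LEADS, ]
    ids[i] <- r$id
    if (D > 0)
      M[i, ] <- one_hot_metadata(discretize_metadata(r$meta), features)
  }
  structure(list(X = X, Y = Y, M = M, ids = ids,
                 split = if (is.null(split)) NULL else as.factor(split),
                 features = features, fs = target_fs),
            class = "windowed_pairs")
}

#' @export
print.windowed_pairs <- function(x, ...) {
  cat(sprintf("<windowed_pairs> n=%d, window=%d @ %g Hz, metadata D=%d\n",
              nrow(x$X), ncol(x$X), x$fs, ncol(x$M)))
  invisible(x)
}

#' Subset windowed pairs by index or split label
#' @param pairs a `windowed_pairs` object.
#' @param which integer/logical index, or one of `"train"`, `"val"`,
#'   `"test"` (requires a `split`).
#' @return A `windowed_pairs` object.
#' @export
pairs_subset <- function(pairs, which) {
  idx <- if (is.character(which)) {
    if (is.null(pairs$split)) stop("pairs carry no split assignment")
    which(pairs$split == which)
  } else which
  structure(list(X = pairs$X[idx, , drop = FALSE],
                 Y = pairs$Y[idx, , , drop = FALSE],
                 M = pairs$M[idx, , drop = FALSE],
                 ids = pairs$ids[idx],
                 split = if (is.null(pairs$split)) NULL else pairs$split[idx],
                 features = pairs$features, fs = pairs$fs),
            class = "windowed_pairs")
}
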