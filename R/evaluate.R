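# Fidelity metrics (Pearson R, RMSE, 1-D SSIM), R-peak detection,
# segment-wise analysis, and the paired statistical comparison protocol.

#' Pearson correlation between reconstructed and reference signals
#'
#' @param pred,ref numeric vectors of equal length (>= 2).
#' @return Pearson product-moment correlation; `NA` if either input is
#'   constant.
#' @export
pearson_r <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("lengths differ")
  if (length(pred) < 2) stop("need at least 2 samples")
  if (stats::sd(pred) == 0 || stats::sd(ref) == 0) return(NA_real_)
  stats::cor(pred, ref)
}

#' Root mean square error
#' @param pred,ref numeric vectors/arrays of equal length (mV).
#' @return RMSE in mV.
#' @export
rmse <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("lengths differ")
  sqrt(mean((pred - ref)^2))
}

#' Structural similarity index for 1-D signals
#'
#' Sliding-window SSIM with a Gaussian window (default 11 samples,
#' sigma 1.5), constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L` the
#' data range of the reference (unless overridden), population-weighted
#' covariances, averaged over all fully supported window positions.
#'
#' @param pred,ref numeric vectors of equal length >= `window`.
#' @param window odd window length in samples.
#' @param sigma Gaussian window SD in samples.
#' @param data_range dynamic range `L`; defaults to `max(ref) - min(ref)`.
#' @return Mean SSIM (<= 1; 1 iff `pred == ref`); `NA` if the data range
#'   is zero.
#' @export
ssim_1d <- function(pred, ref, window = 11L, sigma = 1.5,
                    data_range = NULL) {
  n <- length(ref)
  if (length(pred) != n) stop("lengths differ")
  if (n < window) stop("signal shorter than the SSIM window")
  if (is.null(data_range)) data_range <- max(ref) - min(ref)
  if (data_range <= 0) return(NA_real_)
  r <- (window - 1L) %/% 2L
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  centers <- (r + 1L):(n - r)
  vals <- vapply(centers, function(j) {
    idx <- (j - r):(j + r)
    x <- pred[idx]; y <- ref[idx]
    mx <- sum(w * x); my <- sum(w * y)
    vx <- sum(w * x * x) - mx^2
    vy <- sum(w * y * y) - my^2
    cxy <- sum(w * x * y) - mx * my
    ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }, numeric(1))
  mean(vals)
}

#' Detect R peaks with a derivative-energy detector
#'
#' Differencing, squaring and a 150-ms moving integration window produce a
#' QRS energy envelope; candidate maxima above an adaptive threshold
#' (fraction of the 99th-percentile envelope) are accepted greedily with a
#' 200-ms refractory period, then each peak is refined to the largest
#' absolute deflection of the original signal within +/- 100 ms.
#'
#' @param x numeric signal (mV).
#' @param fs sampling rate in Hz.
#' @param threshold_frac adaptive threshold as a fraction of the
#'   99th-percentile envelope energy.
#' @return Sorted integer sample indices of R peaks (empty, with a
#'   warning, when nothing crosses the threshold).
#' @export
detect_r_peaks <- function(x, fs, threshold_frac = 0.3) {
  n <- length(x)
  if (n < 2 * fs) stop("need at least 2 s of signal")
  d <- c(0, diff(x))
  energy <- d^2
  w <- max(3L, round(0.15 * fs))
  integ <- stats::filter(energy, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  top <- stats::quantile(integ, 0.99)
  if (top <= 0) {
    warning("no QRS energy found")
    return(integer(0))
  }
  thr <- threshold_frac * top
  cand <- which(integ > thr &
                integ >= c(-Inf, integ[-n]) &
                integ >= c(integ[-1], -Inf))
  if (length(cand) == 0) {
    warning("no QRS energy above threshold")
    return(integer(0))
  }
  refr <- round(0.2 * fs)
  cand <- cand[order(integ[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand)
    if (all(abs(kept - p) > refr)) kept <- c(kept, p)
  # refine to the largest absolute deflection of the raw signal
  half <- round(0.1 * fs)
  base <- stats::median(x)
  kept <- vapply(kept, function(p) {
    i0 <- max(1L, p - half); i1 <- min(n, p + half)
    as.integer(i0 + which.max(abs(x[i0:i1] - base)) - 1L)
  }, integer(1))
  sort(unique(kept))
}

#' Default segment windows relative to the R peak
#'
#' Offsets in ms: P wave \[-240, -100), QRS complex \[-60, +60\],
#' ST segment (+60, +160\], T wave (+160, +420\].  The four windows are
#' disjoint by construction.
#'
#' @return Named list of length-2 numeric vectors (ms).
#' @export
segment_windows <- function() {
  list(P = c(-240, -100), QRS = c(-60, 60), ST = c(60, 160), T = c(160, 420))
}

# integer sample offsets for each segment at sampling rate fs, honouring
# the open/closed boundary conventions documented in segment_windows()
.segment_offsets <- function(windows, fs) {
  ms2s <- function(ms) round(ms * fs / 1000)
  list(P = seq(ms2s(windows$P[1]), ms2s(windows$P[2]) - 1L),
       QRS = seq(ms2s(windows$QRS[1]), ms2s(windows$QRS[2])),
       ST = seq(ms2s(windows$ST[1]) + 1L, ms2s(windows$ST[2])),
       T = seq(ms2s(windows$T[1]) + 1L, ms2s(windows$T[2])))
}

#' Segment-wise reconstruction correlation (P / QRS / ST / T)
#'
#' For each segment type, samples from that window of every complete beat
#' (beats whose windows fall entirely inside the record are kept) are
#' concatenated across beats; one Pearson R is computed per lead and then
#' averaged over leads.
#'
#' @param pred,ref 11 x T matrices in target-lead order.
#' @param peaks R-peak sample indices in the reference (see
#'   [detect_r_peaks()]).
#' @param windows segment windows in ms (default [segment_windows()]).
#' @param fs sampling rate (Hz).
#' @return List with `per_segment` (named vector P, QRS, ST, T, Ave) and
#'   `per_lead` (4 x 11 matrix of per-lead correlations).
#' @export
segment_correlations <- function(pred, ref, peaks,
                                 windows = segment_windows(), fs = 100) {
  stopifnot(nrow(pred) == 11, identical(dim(pred), dim(ref)))
  T <- ncol(ref)
  offs <- .segment_offsets(windows, fs)
  per_lead <- matrix(NA_real_, 4, 11,
                     dimnames = list(names(offs), TARGET_LEADS))
  for (sg in names(offs)) {
    o <- offs[[sg]]
    keep <- peaks[peaks + min(o) >= 1 & peaks + max(o) <= T]
    if (length(keep) == 0) next
    idx <- as.vector(outer(o, keep, "+"))
    for (l in seq_len(11)) {
      p <- pred[l, idx]; r <- ref[l, idx]
      if (stats::sd(p) > 0 && stats::sd(r) > 0)
        per_lead[sg, l] <- stats::cor(p, r)
    }
  }
  per_segment <- rowMeans(per_lead, na.rm = TRUE)
  per_segment <- c(per_segment, Ave = mean(per_segment, na.rm = TRUE))
  list(per_segment = per_segment, per_lead = per_lead)
}

#' Evaluate reconstructions against references
#'
#' Computes per-record, per-lead Pearson R, RMSE and 1-D SSIM, aggregated
#' as mean +/- SD across records (per lead and overall), plus optional
#' segment-wise correlations anchored on R peaks detected in reference
#' Lead II.
#'
#' @param pred n x 11 x T array of reconstructions (target-lead order).
#' @param pairs the matching `windowed_pairs` (provides references).
#' @param segments also compute P/QRS/ST/T segment correlations?
#' @param label condition label stored in the report.
#' @return An object of class `eval_report`: list with `per_record`
#'   (data frame of record-mean R/RMSE/SSIM), `per_lead` (lead x metric
#'   summary), `overall` (mean +/- SD per metric), and optionally
#'   `segments`.
#' @export
evaluate_reconstruction <- function(pred, pairs, segments = FALSE,
                                    label = "model") {
  n <- nrow(pairs$X); T <- ncol(pairs$X)
  stopifnot(identical(dim(pred), c(n, 11L, T)))
  Rm <- matrix(NA_real_, n, 11); Em <- matrix(NA_real_, n, 11)
  Sm <- matrix(NA_real_, n, 11)
  seg_acc <- matrix(0, 4, 11); seg_cnt <- matrix(0, 4, 11)
  for (i in seq_len(n)) {
    ref <- pairs$Y[i, , ]; prd <- pred[i, , ]
    for (l in seq_len(11)) {
      Rm[i, l] <- pearson_r(prd[l, ], ref[l, ])
      Em[i, l] <- rmse(prd[l, ], ref[l, ])
      Sm[i, l] <- ssim_1d(prd[l, ], ref[l, ])
    }
    if (segments) {
      pk <- suppressWarnings(detect_r_peaks(ref[1, ], pairs$fs))
      if (length(pk) > 0) {
        sc <- segment_correlations(prd, ref, pk, fs = pairs$fs)
        ok <- !is.na(sc$per_lead)
        seg_acc[ok] <- seg_acc[ok] + sc$per_lead[ok]
        seg_cnt <- seg_cnt + ok
      }
    }
  }
  colnames(Rm) <- colnames(Em) <- colnames(Sm) <- TARGET_LEADS
  agg <- function(m) data.frame(
    lead = TARGET_LEADS,
    mean = colMeans(m, na.rm = TRUE),
    sd = apply(m, 2, stats::sd, na.rm = TRUE))
  per_record <- data.frame(id = pairs$ids,
                           R = rowMeans(Rm, na.rm = TRUE),
                           RMSE = rowMeans(Em, na.rm = TRUE),
                           SSIM = rowMeans(Sm, na.rm = TRUE))
  overall <- data.frame(
    metric = c("R", "RMSE", "SSIM"),
    mean = c(mean(per_record$R, na.rm = TRUE),
             mean(per_record$RMSE, na.rm = TRUE),
             mean(per_record$SSIM, na.rm = TRUE)),
    sd = c(stats::sd(per_record$R, na.rm = TRUE),
           stats::sd(per_record$RMSE, na.rm = TRUE),
           stats::sd(per_record$SSIM, na.rm = TRUE)))
  rep <- list(label = label, per_record = per_record,
              per_lead = list(R = agg(Rm), RMSE = agg(Em), SSIM = agg(Sm)),
              overall = overall)
  if (segments) {
    seg <- seg_acc / pmax(seg_cnt, 1)
    seg[seg_cnt == 0] <- NA_real_
    dimnames(seg) <- list(c("P", "QRS", "ST", "T"), TARGET_LEADS)
    per_segment <- rowMeans(seg, na.rm = TRUE)
    rep$segments <- list(per_lead = seg,
                         per_segment = c(per_segment,
                                         Ave = mean(per_segment, na.rm = TRUE)))
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report '%s'> n = %d records\n", x$label,
              nrow(x$per_record)))
  for (i in seq_len(nrow(x$overall)))
    cat(sprintf("  %-5s %.3f +/- %.3f\n", x$overall$metric[i],
                x$overall$mean[i], x$overall$sd[i]))
  if (!is.null(x$segments)) {
    cat("  segment R:",
        paste(names(x$segments$per_segment),
              sprintf("%.3f", x$segments$per_segment), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Paired statistical comparison of two models
#'
#' For each metric, the per-record paired values are compared with a
#' Wilcoxon signed-rank test (R and SSIM) or a paired t-test (RMSE), and
#' the raw p-values are Holm-adjusted over the declared comparison family;
#' flags are set at `alpha`.
#'
#' @param reports_a,reports_b `eval_report` objects (or lists with a
#'   `per_record` data frame) from the same records in the same order.
#' @param metrics metrics to compare (subset of R, RMSE, SSIM).
#' @param alpha family-wise significance level.
#' @return Data frame with columns `metric`, `test`, `n`, `p_raw`,
#'   `p_holm`, `significant`.
#' @export
compare_models <- function(reports_a, reports_b,
                           metrics = c("R", "RMSE", "SSIM"), alpha = 0.05) {
  a <- reports_a$per_record; b <- reports_b$per_record
  if (nrow(a) != nrow(b)) stop("reports must pair the same records")
  res <- data.frame(metric = metrics,
                    test = ifelse(metrics == "RMSE", "paired t",
                                  "Wilcoxon signed-rank"),
                    n = nrow(a), p_raw = NA_real_)
  for (i in seq_along(metrics)) {
    m <- metrics[i]
    diffs <- a[[m]] - b[[m]]
    diffs <- diffs[is.finite(diffs)]
    res$n[i] <- length(diffs)
    if (all(diffs == 0)) next                       # test undefined
    res$p_raw[i] <- if (m == "RMSE")
      stats::t.test(diffs)$p.value
    else
      suppressWarnings(stats::wilcox.test(diffs, exact = FALSE)$p.value)
  }
  res$p_holm <- stats::p.adjust(res$p_raw, method = "holm")
  res$significant <- !is.na(res$p_holm) & res$p_holm < alpha
  res
}
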