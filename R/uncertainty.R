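# Monte Carlo dropout predictive uncertainty and reliability analysis.
#
# N stochastic forward passes are run with the two designated dropout sites
# (after the BiLSTM block and after the fusion concatenation) active.  The
# per-time-point predictive standard deviation uses the population (divisor
# N) form; the normalized deviation divides each lead by its temporal
# maximum; the relative error is |pred - ref| / (|ref| + eps) by default.

#' Monte Carlo dropout forward passes
#'
#' Runs `N` stochastic forward passes with the model's dropout sites active
#' and returns the sample stack plus its mean.  Passes are batched
#' internally; each pass draws an independent dropout mask.
#'
#' @param object an `ecg_recon` fit or `ecg_recon_net`.
#' @param lead1 numeric Lead I window (length 512), or a matrix `1 x 512`.
#' @param meta one-hot metadata vector of length D (ignored when the model
#'   was fit without metadata).
#' @param N number of stochastic passes (>= 2; the reference protocol uses
#'   1000).
#' @param seed integer seed (required).
#' @param chunk passes evaluated per internal batch.
#' @return An object of class `mc_stack`: list with `samples`
#'   (N x 11 x 512), `mean` (11 x 512), `N`, `seed`.
#' @export
mc_predict <- function(object, lead1, meta = numeric(0), N = 1000L, seed,
                       chunk = 50L) {
  net <- if (inherits(object, "ecg_recon")) object$net else object
  if (N < 2) stop("N must be >= 2")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  X1 <- matrix(as.numeric(lead1), 1)
  M1 <- matrix(as.numeric(meta), 1)[, seq_len(net$metadata_dim), drop = FALSE]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  samples <- array(0, c(N, 11L, ncol(X1)))
  done <- 0L
  while (done < N) {
    b <- min(chunk, N - done)
    Xb <- X1[rep(1L, b), , drop = FALSE]
    Mb <- M1[rep(1L, b), , drop = FALSE]
    fw <- net_forward(net, Xb, Mb, dropout_active = TRUE, cache = FALSE)
    samples[done + seq_len(b), , ] <- fw$Y
    done <- done + b
  }
  structure(list(samples = samples,
                 mean = apply(samples, c(2, 3), mean),
                 N = as.integer(N), seed = as.integer(seed)),
            class = "mc_stack")
}

#' @export
print.mc_stack <- function(x, ...) {
  cat(sprintf("<mc_stack> N=%d stochastic passes, 11 x %d output\n",
              x$N, dim(x$samples)[3]))
  invisible(x)
}

#' Predictive standard deviation of an MC sample stack
#'
#' Population form: `sigma(t) = sqrt(mean_i (y_i(t) - ybar(t))^2)` with
#' divisor N, per lead and time point.
#'
#' @param stack an [mc_predict()] result.
#' @return An object of class `uncertainty_profile`: list with `sigma`
#'   (11 x T, mV) and `sigma_norm` (`NULL` until [normalize_std()]).
#' @export
predictive_std <- function(stack) {
  stopifnot(inherits(stack, "mc_stack"))
  dev <- sweep(stack$samples, c(2, 3), stack$mean)
  sigma <- sqrt(apply(dev^2, c(2, 3), mean))
  rownames(sigma) <- TARGET_LEADS
  structure(list(sigma = sigma, sigma_norm = NULL, N = stack$N),
            class = "uncertainty_profile")
}

#' Normalize predictive deviation by its temporal maximum per lead
#'
#' Each lead's sigma trace is divided by its own maximum over time, so the
#' normalized profile attains 1 somewhere on every lead; a lead with
#' identically zero sigma maps to all zeros (documented convention).
#'
#' @param profile a [predictive_std()] result.
#' @return The profile with `sigma_norm` filled (values in \[0, 1\]).
#' @export
normalize_std <- function(profile) {
  stopifnot(inherits(profile, "uncertainty_profile"))
  mx <- apply(profile$sigma, 1, max)
  sn <- profile$sigma / ifelse(mx > 0, mx, 1)
  sn[mx == 0, ] <- 0
  profile$sigma_norm <- sn
  profile
}

#' Relative reconstruction error
#'
#' Default (absolute-value convention): `e(t) = |pred - ref| /
#' (|ref| + eps)`; `signed = TRUE` gives `(pred - ref) / (|ref| + eps)`.
#' `eps` stabilizes near-zero reference samples.
#'
#' @param pred,ref numeric arrays of identical shape (mV).
#' @param eps stability constant (> 0, default 1e-3 mV).
#' @param signed keep the sign of the error?
#' @return Array of relative errors, same shape as `pred`.
#' @export
relative_error <- function(pred, ref, eps = 1e-3, signed = FALSE) {
  if (!identical(dim(pred), dim(ref)) || length(pred) != length(ref))
    stop("pred and ref must have identical shape")
  if (eps <= 0) stop("eps must be > 0")
  e <- (pred - ref) / (abs(ref) + eps)
  if (signed) e else abs(e)
}

.lead_rows <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- TARGET_LEADS
  m
}

.pool_lead_points <- function(profiles, errors) {
  profiles <- lapply(profiles, function(p) {
    p$sigma_norm <- .lead_rows(p$sigma_norm); p
  })
  errors <- lapply(errors, .lead_rows)
  leads <- TARGET_LEADS
  pooled <- stats::setNames(vector("list", length(leads)), leads)
  for (ld in leads) {
    s <- unlist(lapply(profiles, function(p) p$sigma_norm[ld, ]))
    e <- unlist(lapply(errors, function(e) e[ld, ]))
    pooled[[ld]] <- list(s = s, e = e)
  }
  pooled
}

#' Per-lead correlation between normalized uncertainty and relative error
#'
#' All record-by-time-point pairs are pooled per lead (the default) and a
#' single Pearson correlation computed; `per_record = TRUE` instead
#' computes one correlation per record and averages.
#'
#' @param profiles list of normalized [uncertainty_profile]s (one per
#'   record).
#' @param errors list of 11 x T relative-error matrices, aligned with
#'   `profiles`.
#' @param per_record average per-record correlations instead of pooling?
#' @return Named numeric vector of per-lead correlations (`NA` where either
#'   variable has zero variance).
#' @export
uncertainty_error_correlation <- function(profiles, errors,
                                          per_record = FALSE) {
  stopifnot(length(profiles) == length(errors), length(profiles) >= 1)
  leads <- TARGET_LEADS
  profiles <- lapply(profiles, function(p) {
    p$sigma_norm <- .lead_rows(p$sigma_norm); p
  })
  errors <- lapply(errors, .lead_rows)
  if (per_record) {
    per <- sapply(leads, function(ld) {
      rs <- mapply(function(p, e) {
        s <- p$sigma_norm[ld, ]; er <- e[ld, ]
        if (stats::sd(s) == 0 || stats::sd(er) == 0) NA_real_
        else stats::cor(s, er)
      }, profiles, errors)
      mean(rs, na.rm = TRUE)
    })
    return(per)
  }
  pooled <- .pool_lead_points(profiles, errors)
  sapply(pooled, function(p) {
    if (length(p$s) < 2 || stats::sd(p$s) == 0 || stats::sd(p$e) == 0)
      NA_real_
    else stats::cor(p$s, p$e)
  })
}

#' Quantile-binned relative error by predictive uncertainty
#'
#' All pooled data points (records x leads x time) are ranked by
#' `sigma_norm` (stable order; ties broken by original position) and split
#' into `n_bins` equal-size bins (Q1 = lowest uncertainty); per-bin mean
#' and SD of the relative error and the mean uncertainty are reported.
#'
#' @inheritParams uncertainty_error_correlation
#' @param n_bins number of quantile bins (default 4).
#' @return Data frame with columns `quantile`, `n`, `mean_sigma_norm`,
#'   `mean_error`, `sd_error`.
#' @export
quantile_error_table <- function(profiles, errors, n_bins = 4L) {
  s <- unlist(lapply(profiles, function(p) as.vector(p$sigma_norm)))
  e <- unlist(lapply(errors, as.vector))
  if (length(s) < n_bins) stop("need at least n_bins pooled points")
  ord <- order(s)                                   # stable in base R
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  bin <- pmin(bin, n_bins)
  out <- data.frame(quantile = paste0("Q", seq_len(n_bins)),
                    n = as.integer(tabulate(bin, n_bins)))
  out$mean_sigma_norm <- vapply(seq_len(n_bins),
                                function(b) mean(s[ord][bin == b]), 0)
  out$mean_error <- vapply(seq_len(n_bins),
                           function(b) mean(e[ord][bin == b]), 0)
  out$sd_error <- vapply(seq_len(n_bins),
                         function(b) stats::sd(e[ord][bin == b]), 0)
  out
}

#' Render an uncertainty heatmap for reconstructed leads
#'
#' Predicted and reference traces are overlaid on a background coloured by
#' the normalized predictive uncertainty (blue = low, red = high), one
#' panel per requested lead.
#'
#' @param pred,ref 11 x T matrices (mV), rows in target-lead order.
#' @param sigma_norm 11 x T normalized uncertainty matrix.
#' @param out_path output PNG path.
#' @param leads character vector of target leads to draw.
#' @param fs sampling rate of the window (Hz), for the time axis.
#' @return `out_path`, invisibly.
#' @export
render_heatmap <- function(pred, ref, sigma_norm, out_path,
                           leads = c("II", "V6"), fs = 100) {
  stopifnot(all(leads %in% TARGET_LEADS))
  rownames(pred) <- rownames(ref) <- rownames(sigma_norm) <- TARGET_LEADS
  T <- ncol(pred)
  tt <- (seq_len(T) - 1) / fs
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(100)
  grDevices::png(out_path, width = 900, height = 280 * length(leads))
  op <- graphics::par(mfrow = c(length(leads), 1), mar = c(3.5, 4, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  for (ld in leads) {
    yl <- range(pred[ld, ], ref[ld, ])
    yl <- yl + c(-0.1, 0.1) * diff(yl)
    graphics::image(tt, seq(yl[1], yl[2], length.out = 2),
                    matrix(sigma_norm[ld, ], ncol = 1), col = pal,
                    zlim = c(0, 1), xlab = "time [s]", ylab = "mV",
                    main = paste("Lead", ld), useRaster = TRUE)
    graphics::lines(tt, ref[ld, ], col = "grey30", lwd = 1.5)
    graphics::lines(tt, pred[ld, ], col = "black", lwd = 1.2)
  }
  invisible(out_path)
}
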