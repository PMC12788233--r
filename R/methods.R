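# S3 methods for fitted reconstruction models.

#' @export
print.ecg_recon <- function(x, ...) {
  kind <- c(dual = "dual-branch CNN-BiLSTM",
            earlyfusion = "early-fusion CNN-BiLSTM",
            unet = "1-D U-Net")[x$net$kind]
  cat(sprintf("<ecg_recon> %s, metadata D = %d\n", kind, x$net$metadata_dim))
  if (length(x$features))
    cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  trained %d epochs on %d records (val %d)\n",
              x$config$epochs, x$n_train, x$n_val))
  cat(sprintf("  best epoch %s, validation MSE %.6g mV^2\n",
              x$best$epoch, x$best$val_loss))
  invisible(x)
}

#' @export
summary.ecg_recon <- function(object, ...) {
  h <- object$history
  structure(list(fit = object,
                 final_train_loss = h$train_loss[nrow(h)],
                 best = object$best,
                 n_params = sum(vapply(object$net$params, length, 0)),
                 val_epochs = h$epoch[!is.na(h$val_loss)]),
            class = "summary.ecg_recon")
}

#' @export
print.summary.ecg_recon <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  parameters: %d\n", x$n_params))
  cat(sprintf("  final train MSE %.6g mV^2; validation at epochs %s\n",
              x$final_train_loss, paste(x$val_epochs, collapse = ", ")))
  invisible(x)
}

#' @export
coef.ecg_recon <- function(object, ...) object$net$params

#' Predict 11-lead reconstructions
#'
#' Deterministic forward pass (dropout inactive).
#'
#' @param object an `ecg_recon` fit.
#' @param newdata a `windowed_pairs` object, or a list with `X` (n x 512)
#'   and `M` (n x D).
#' @param ... unused.
#' @return n x 11 x 512 array (mV), leads in target order on dimnames.
#' @export
predict.ecg_recon <- function(object, newdata, ...) {
  X <- newdata$X; M <- newdata$M
  if (is.null(M)) M <- matrix(0, nrow(X), 0)
  if (ncol(M) != object$net$metadata_dim)
    stop(sprintf("metadata dimension mismatch: model expects %d, got %d",
                 object$net$metadata_dim, ncol(M)))
  out <- predict_net(object$net, X, M)
  dimnames(out) <- list(NULL, TARGET_LEADS, NULL)
  out
}

#' @export
residuals.ecg_recon <- function(object, newdata, ...) {
  predict(object, newdata) - newdata$Y
}

#' Monte Carlo dropout draws from a fitted reconstruction model
#'
#' `simulate` performs `nsim` stochastic forward passes for one record of
#' `newdata` with the dropout sites active (see [mc_predict()]).
#'
#' @param object an `ecg_recon` fit.
#' @param nsim number of stochastic passes.
#' @param seed integer seed (required).
#' @param newdata a `windowed_pairs` object.
#' @param index which record of `newdata` to simulate.
#' @param ... unused.
#' @return An `mc_stack` (see [mc_predict()]).
#' @export
simulate.ecg_recon <- function(object, nsim = 100L, seed = NULL,
                               newdata, index = 1L, ...) {
  if (is.null(seed)) stop("a seed is required")
  mc_predict(object, newdata$X[index, ], newdata$M[index, ], N = nsim,
             seed = seed)
}

#' Plot training history or a reconstruction overlay
#'
#' @param x an `ecg_recon` fit.
#' @param which `"history"` (loss curves) or `"fit"` (overlay of predicted
#'   and reference leads for one record).
#' @param newdata `windowed_pairs`, required for `which = "fit"`.
#' @param index record index for the overlay.
#' @param leads leads to draw in the overlay.
#' @param ... passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.ecg_recon <- function(x, which = c("history", "fit"), newdata = NULL,
                           index = 1L, leads = c("II", "V2"), ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$history
    graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                   ylab = "MSE [mV^2]", main = "training history", ...)
    ok <- !is.na(h$val_loss)
    if (any(ok))
      graphics::points(h$epoch[ok], h$val_loss[ok], pch = 19, col = "red")
    graphics::legend("topright", c("train", "validation"),
                     lty = c(1, NA), pch = c(NA, 19),
                     col = c("black", "red"), bty = "n")
  } else {
    if (is.null(newdata)) stop("newdata is required for which = 'fit'")
    pred <- predict(x, newdata)
    tt <- (seq_len(ncol(newdata$X)) - 1) / newdata$fs
    op <- graphics::par(mfrow = c(length(leads), 1), mar = c(3.5, 4, 2, 1))
    on.exit(graphics::par(op))
    for (ld in leads) {
      li <- match(ld, TARGET_LEADS)
      graphics::plot(tt, newdata$Y[index, li, ], type = "l", col = "grey40",
                     xlab = "time [s]", ylab = "mV",
                     main = paste("Lead", ld), ...)
      graphics::lines(tt, pred[index, li, ], col = "red")
    }
  }
  invisible(x)
}
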