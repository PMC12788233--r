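# Training loop (Adam, MSE), prediction, checkpoints.

.mse_loss <- function(Y, T_) mean((Y - T_)^2)

# deterministic batched forward without dropout
predict_net <- function(net, X, M, batch = 128L) {
  n <- nrow(X)
  out <- array(0, c(n, 11L, ncol(X)))
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    out[i:j, , ] <- net_forward(net, X[i:j, , drop = FALSE],
                                M[i:j, , drop = FALSE])$Y
    i <- j + 1L
  }
  out
}

.eval_mse <- function(net, pairs, batch = 128L) {
  .mse_loss(predict_net(net, pairs$X, pairs$M, batch), pairs$Y)
}

#' Train a reconstruction network
#'
#' Minimizes MSE with Adam at `cfg$learning_rate`, batch size
#' `cfg$batch_size`, shuffling the training set every epoch (seeded).
#' Validation loss is computed (dropout off) at every
#' `cfg$validation_interval`-th epoch and at the final epoch; the returned
#' parameters are those of the epoch with the lowest validation loss.
#'
#' @param net an untrained `ecg_recon_net` from one of the builders.
#' @param train_pairs,val_pairs `windowed_pairs` objects; `val_pairs` may be
#'   `NULL` (final parameters are then kept).
#' @param cfg a [model_config()] (defaults to the one stored in `net`).
#' @param verbose print per-epoch losses?
#' @return The trained `ecg_recon_net` with `history` (data frame of epoch,
#'   train and validation loss) and `best` (epoch index and loss).
#' @export
train_model <- function(net, train_pairs, val_pairs = NULL, cfg = net$cfg,
                        verbose = FALSE) {
  n <- nrow(train_pairs$X)
  if (n == 0) stop("empty training set")
  if (!is.null(val_pairs) && nrow(val_pairs$X) == 0) val_pairs <- NULL
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  adam <- adam_init(net$params)
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     val_loss = NA_real_)
  best <- list(epoch = NA_integer_, val_loss = Inf, params = NULL)
  for (epoch in seq_len(cfg$epochs)) {
    set.seed(as.integer(cfg$seed) * 1000L + epoch)
    perm <- sample.int(n)
    tot <- 0
    i <- 1L
    while (i <= n) {
      idx <- perm[i:min(i + cfg$batch_size - 1L, n)]
      fw <- net_forward(net, train_pairs$X[idx, , drop = FALSE],
                        train_pairs$M[idx, , drop = FALSE],
                        dropout_active = TRUE, cache = TRUE, raw = TRUE)
      T_ <- .array_to_seqmat(train_pairs$Y[idx, , , drop = FALSE])
      loss <- .mse_loss(fw$Y, T_)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d (lr too high?)", epoch))
      dY <- 2 * (fw$Y - T_) / length(T_)
      grads <- net_backward(net, dY, fw$cache)
      st <- adam_step(net$params, grads, adam, cfg$learning_rate)
      net$params <- st$params; adam <- st$state
      tot <- tot + loss * length(idx)
      i <- i + cfg$batch_size
    }
    hist$train_loss[epoch] <- tot / n
    do_val <- !is.null(val_pairs) &&
      (epoch %% cfg$validation_interval == 0L || epoch == cfg$epochs)
    if (do_val) {
      vl <- .eval_mse(net, val_pairs)
      hist$val_loss[epoch] <- vl
      if (vl < best$val_loss)
        best <- list(epoch = epoch, val_loss = vl, params = net$params)
    }
    if (verbose)
      cat(sprintf("epoch %3d  train %.6f%s\n", epoch, hist$train_loss[epoch],
                  if (do_val) sprintf("  val %.6f", hist$val_loss[epoch]) else ""))
  }
  if (!is.null(best$params)) {
    net$params <- best$params
    net$best <- best[c("epoch", "val_loss")]
  } else {
    net$best <- list(epoch = cfg$epochs,
                     val_loss = hist$train_loss[cfg$epochs])
  }
  net$history <- hist
  net
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing list (model kind, config snapshot,
#' metadata dimension, parameters, training history, best epoch) written
#' with `saveRDS`.
#'
#' @param net a trained `ecg_recon_net` or an `ecg_recon` fit.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored object.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Fit a 12-lead reconstruction model from windowed Lead I pairs
#'
#' The main fitting entry point.  `pairs` is a [make_windowed_pairs()]
#' result; when it carries a split assignment the `train` portion is used
#' for fitting and the `val` portion for checkpoint selection, otherwise
#' all pairs train and `val_pairs` may be supplied separately.
#'
#' @param pairs a `windowed_pairs` object.
#' @param model `"dual"` (dual-branch CNN-BiLSTM), `"earlyfusion"`
#'   (same backbone, channel-concatenated metadata) or `"unet"` (1-D U-Net
#'   baseline).
#' @param config a [model_config()].
#' @param val_pairs optional explicit validation `windowed_pairs`.
#' @param verbose print training progress?
#' @return An object of class `ecg_recon` with methods `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `simulate` (Monte Carlo dropout
#'   draws) and `plot`.
#' @export
ecg_reconstruct <- function(pairs, model = c("dual", "earlyfusion", "unet"),
                            config = model_config(), val_pairs = NULL,
                            verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(pairs, "windowed_pairs"))
  if (!is.null(pairs$split)) {
    train <- pairs_subset(pairs, "train")
    if (is.null(val_pairs) && any(pairs$split == "val"))
      val_pairs <- pairs_subset(pairs, "val")
  } else train <- pairs
  D <- ncol(pairs$M)
  net <- switch(model,
                dual = build_dual_branch(config, D),
                earlyfusion = build_early_fusion_baseline(config, D),
                unet = build_unet_baseline(config, D))
  net <- train_model(net, train, val_pairs, config, verbose = verbose)
  structure(list(net = net, config = config, features = pairs$features,
                 history = net$history, best = net$best,
                 n_train = nrow(train$X),
                 n_val = if (is.null(val_pairs)) 0L else nrow(val_pairs$X),
                 call = match.call()),
            class = "ecg_recon")
}
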