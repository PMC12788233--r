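# Reconstruction networks: dual-branch CNN-BiLSTM, early-fusion CNN-BiLSTM,
# and a 1-D U-Net baseline.  All map a 1 x 512 Lead I window (plus a
# D-dimensional one-hot metadata vector) to an 11 x 512 target.

#' Model configuration
#'
#' Defaults are the final configuration of the reconstruction network: a
#' two-layer convolutional front-end with 32 filters and kernel size 5, a
#' BiLSTM with 512 units, dropout 0.2 after the BiLSTM and after the fusion
#' concatenation, a three-layer fully connected feature branch, one hidden
#' time-distributed fusion layer of width 256, Adam with learning rate
#' 0.001, 100 epochs, batch size 32, validation every 20 epochs.
#'
#' @param conv_layers,conv_filters,kernel_size convolutional front-end.
#' @param bilstm_units hidden units per LSTM direction.
#' @param dropout_rate dropout probability in \[0, 1).
#' @param feature_fc_layers,feature_fc_width metadata branch depth/width.
#' @param fusion_fc_widths integer vector of hidden widths in the
#'   time-distributed fusion head (before the 11-unit linear output).
#' @param learning_rate,epochs,batch_size,validation_interval training
#'   hyperparameters; validation runs at multiples of
#'   `validation_interval` and at the final epoch.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class `model_config` (named list).
#' @export
model_config <- function(conv_layers = 2L, conv_filters = 32L,
                         kernel_size = 5L, bilstm_units = 512L,
                         dropout_rate = 0.2, feature_fc_layers = 3L,
                         feature_fc_width = 32L, fusion_fc_widths = 256L,
                         learning_rate = 0.001, epochs = 100L,
                         batch_size = 32L, validation_interval = 20L,
                         seed = 1L) {
  stopifnot(conv_layers >= 1, conv_filters >= 1, kernel_size >= 1,
            bilstm_units >= 1, dropout_rate >= 0, dropout_rate < 1,
            feature_fc_layers >= 1, feature_fc_width >= 1,
            learning_rate > 0, epochs >= 1, batch_size >= 1,
            validation_interval >= 1)
  structure(as.list(environment()), class = "model_config")
}

.build_common <- function(cfg, in_channels) {
  K <- cfg$kernel_size; F <- cfg$conv_filters
  p <- list()
  cin <- in_channels
  for (l in seq_len(cfg$conv_layers)) {
    p[[paste0("conv", l, "_W")]] <- glorot_init(cin * K, F)
    p[[paste0("conv", l, "_b")]] <- rep(0, F)
    cin <- F
  }
  lp <- bilstm_init(F, cfg$bilstm_units)
  names(lp) <- paste0("lstm_", names(lp))
  c(p, lp)
}

.build_head <- function(cfg, in_dim) {
  p <- list()
  d <- in_dim
  for (i in seq_along(cfg$fusion_fc_widths)) {
    w <- cfg$fusion_fc_widths[i]
    p[[paste0("head", i, "_W")]] <- glorot_init(d, w)
    p[[paste0("head", i, "_b")]] <- rep(0, w)
    d <- w
  }
  p$out_W <- glorot_init(d, 11L)
  p$out_b <- rep(0, 11L)
  p
}

.new_net <- function(kind, cfg, metadata_dim, params) {
  structure(list(kind = kind, cfg = cfg, metadata_dim = metadata_dim,
                 params = params, history = NULL, best = NULL),
            class = "ecg_recon_net")
}

#' Build the dual-branch CNN-BiLSTM reconstruction network (untrained)
#'
#' Time branch: `conv_layers` 1-D convolutions (ReLU) over the 1 x 512
#' input, then a BiLSTM whose per-timestep output is kept (sequence to
#' sequence), then dropout.  Feature branch: `feature_fc_layers` fully
#' connected ReLU layers on the D-dimensional one-hot vector.  Fusion: the
#' feature embedding is broadcast along the 512 time steps, concatenated
#' with the time-branch features (late fusion), dropout applied again, and
#' a time-distributed fully connected head emits the 11 x 512 output.
#' With `metadata_dim = 0` the feature branch is absent (time-series-only
#' configuration).
#'
#' @param cfg a [model_config()].
#' @param metadata_dim one-hot dimension D (>= 0).
#' @return An `ecg_recon_net` (untrained).
#' @export
build_dual_branch <- function(cfg = model_config(), metadata_dim = 16L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(cfg$seed))
  p <- .build_common(cfg, 1L)
  fuse_dim <- 2L * cfg$bilstm_units
  if (metadata_dim > 0) {
    d <- metadata_dim
    for (l in seq_len(cfg$feature_fc_layers)) {
      p[[paste0("feat", l, "_W")]] <- glorot_init(d, cfg$feature_fc_width)
      p[[paste0("feat", l, "_b")]] <- rep(0, cfg$feature_fc_width)
      d <- cfg$feature_fc_width
    }
    fuse_dim <- fuse_dim + cfg$feature_fc_width
  }
  .new_net("dual", cfg, as.integer(metadata_dim), c(p, .build_head(cfg, fuse_dim)))
}

#' Build the early-fusion baseline (untrained)
#'
#' Same CNN-BiLSTM backbone and head as the dual-branch model, but the
#' one-hot metadata vector is repeated along the temporal axis and
#' concatenated with the waveform along the channel dimension, so the first
#' convolution sees `metadata_dim + 1` input channels and there is no
#' separate feature branch.
#'
#' @inheritParams build_dual_branch
#' @return An `ecg_recon_net` (untrained).
#' @export
build_early_fusion_baseline <- function(cfg = model_config(),
                                        metadata_dim = 16L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(cfg$seed))
  p <- .build_common(cfg, 1L + as.integer(metadata_dim))
  .new_net("earlyfusion", cfg, as.integer(metadata_dim),
           c(p, .build_head(cfg, 2L * cfg$bilstm_units)))
}

#' Build the 1-D U-Net baseline (untrained)
#'
#' Depth-3 encoder-decoder with skip connections: channel widths 16/32/64,
#' kernel size 5, max-pooling and nearest-neighbour upsampling by 2, ReLU
#' activations, dropout at the bottleneck, and a kernel-1 linear output
#' convolution.  Metadata enter by channel repetition at the input
#' (`(D + 1) x 512`).
#'
#' @inheritParams build_dual_branch
#' @param base_filters channel width of the first encoder level.
#' @return An `ecg_recon_net` (untrained).
#' @export
build_unet_baseline <- function(cfg = model_config(), metadata_dim = 16L,
                                base_filters = 16L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(cfg$seed))
  K <- cfg$kernel_size; B1 <- base_filters
  cin <- 1L + as.integer(metadata_dim)
  cw <- c(B1, 2L * B1, 4L * B1)
  p <- list(
    e1_W = glorot_init(cin * K, cw[1]), e1_b = rep(0, cw[1]),
    e2_W = glorot_init(cw[1] * K, cw[2]), e2_b = rep(0, cw[2]),
    e3_W = glorot_init(cw[2] * K, cw[3]), e3_b = rep(0, cw[3]),
    mid_W = glorot_init(cw[3] * K, cw[3]), mid_b = rep(0, cw[3]),
    d3_W = glorot_init(2L * cw[3] * K, cw[2]), d3_b = rep(0, cw[2]),
    d2_W = glorot_init(2L * cw[2] * K, cw[1]), d2_b = rep(0, cw[1]),
    d1_W = glorot_init(2L * cw[1] * K, cw[1]), d1_b = rep(0, cw[1]),
    out_W = glorot_init(cw[1] * 1L, 11L), out_b = rep(0, 11L))
  net <- .new_net("unet", cfg, as.integer(metadata_dim), p)
  net$base_filters <- as.integer(base_filters)
  net
}

# ---- forward / backward ----------------------------------------------------
#
# All internals use the seqmat layout of nn.R: a (B*T) x C matrix with row
# b + (t-1)*B.  Channel concatenation is cbind; broadcasting a per-record
# embedding along time is a row replication.

.seqmat_to_array <- function(Ym, B, T) {            # (B*T) x 11 -> B x 11 x T
  aperm(array(Ym, c(B, T, ncol(Ym))), c(1, 3, 2))
}
.array_to_seqmat <- function(Y) {                   # B x 11 x T -> (B*T) x 11
  d <- dim(Y)
  matrix(aperm(Y, c(1, 3, 2)), d[1] * d[3], d[2])
}

.forward_backbone <- function(net, x, B, dropout_active, cache) {
  cfg <- net$cfg; p <- net$params; ch <- list()
  a <- x
  for (l in seq_len(cfg$conv_layers)) {
    cv <- conv1d_forward(a, p[[paste0("conv", l, "_W")]],
                         p[[paste0("conv", l, "_b")]], cfg$kernel_size, B)
    rl <- relu_forward(cv$out)
    ch[[paste0("conv", l)]] <- cv$cache
    ch[[paste0("relu", l)]] <- rl$cache
    a <- rl$out
  }
  lp <- p[grep("^lstm_", names(p))]
  names(lp) <- sub("^lstm_", "", names(lp))
  bl <- bilstm_forward(a, lp, B, cache = cache)
  dr <- dropout_forward(bl$out, cfg$dropout_rate, dropout_active)
  ch$bilstm <- bl$cache; ch$drop1 <- dr$cache
  list(out = dr$out, cache = ch)
}

.backward_backbone <- function(net, dout, ch, B) {
  cfg <- net$cfg; p <- net$params
  grads <- list()
  d <- dropout_backward(dout, ch$drop1)
  lp <- p[grep("^lstm_", names(p))]
  names(lp) <- sub("^lstm_", "", names(lp))
  bb <- bilstm_backward(d, ch$bilstm, lp, B)
  for (nm in names(bb$grads)) grads[[paste0("lstm_", nm)]] <- bb$grads[[nm]]
  d <- bb$dx
  for (l in rev(seq_len(cfg$conv_layers))) {
    d <- relu_backward(d, ch[[paste0("relu", l)]])
    cb <- conv1d_backward(d, ch[[paste0("conv", l)]],
                          p[[paste0("conv", l, "_W")]], cfg$kernel_size, B)
    grads[[paste0("conv", l, "_W")]] <- cb$dW
    grads[[paste0("conv", l, "_b")]] <- cb$db
    d <- cb$dx
  }
  list(dx = d, grads = grads)
}

.forward_head <- function(net, z) {
  cfg <- net$cfg; p <- net$params; ch <- list()
  m <- z
  for (i in seq_along(cfg$fusion_fc_widths)) {
    de <- dense_forward(m, p[[paste0("head", i, "_W")]],
                        p[[paste0("head", i, "_b")]])
    rl <- relu_forward(de$out)
    ch[[paste0("head", i)]] <- de$cache
    ch[[paste0("hrelu", i)]] <- rl$cache
    m <- rl$out
  }
  de <- dense_forward(m, p$out_W, p$out_b)
  ch$out <- de$cache
  list(out = de$out, cache = ch)
}

.backward_head <- function(net, dY, ch) {
  cfg <- net$cfg; grads <- list()
  ob <- dense_backward(dY, ch$out, net$params$out_W)
  grads$out_W <- ob$dW; grads$out_b <- ob$db
  d <- ob$dx
  for (i in rev(seq_along(cfg$fusion_fc_widths))) {
    d <- relu_backward(d, ch[[paste0("hrelu", i)]])
    hb <- dense_backward(d, ch[[paste0("head", i)]],
                         net$params[[paste0("head", i, "_W")]])
    grads[[paste0("head", i, "_W")]] <- hb$dW
    grads[[paste0("head", i, "_b")]] <- hb$db
    d <- hb$dx
  }
  list(dz = d, grads = grads)
}

# full forward pass; X is B x T_w, M is B x D (possibly 0 columns).
# raw = TRUE returns the (B*T) x 11 seqmat output (training path), else a
# B x 11 x T array.
net_forward <- function(net, X, M, dropout_active = FALSE, cache = FALSE,
                        raw = FALSE) {
  B <- nrow(X); T <- ncol(X)
  cfg <- net$cfg; p <- net$params
  wrap <- function(Ym, ch) {
    list(Y = if (raw) Ym else .seqmat_to_array(Ym, B, T),
         cache = if (cache) ch)
  }
  if (net$kind == "unet")
    return(.unet_forward(net, X, M, dropout_active, cache, raw))
  xs <- if (net$kind == "earlyfusion" && net$metadata_dim > 0)
    cbind(matrix(as.vector(X), ncol = 1),
          M[rep(seq_len(B), T), , drop = FALSE])
  else matrix(as.vector(X), ncol = 1)
  bk <- .forward_backbone(net, xs, B, dropout_active, cache)
  ch <- list(backbone = bk$cache, dims = c(B = B, T = T))
  z <- bk$out
  if (net$kind == "dual" && net$metadata_dim > 0) {
    fm <- M; fch <- list()
    for (l in seq_len(cfg$feature_fc_layers)) {
      de <- dense_forward(fm, p[[paste0("feat", l, "_W")]],
                          p[[paste0("feat", l, "_b")]])
      rl <- relu_forward(de$out)
      fch[[paste0("feat", l)]] <- de$cache
      fch[[paste0("frelu", l)]] <- rl$cache
      fm <- rl$out
    }
    ch$feat <- fch
    z <- cbind(z, fm[rep(seq_len(B), T), , drop = FALSE])
  }
  dr <- dropout_forward(z, cfg$dropout_rate, dropout_active)
  ch$drop2 <- dr$cache
  hd <- .forward_head(net, dr$out)
  ch$head <- hd$cache
  wrap(hd$out, ch)
}

# dY in seqmat layout (B*T) x 11
net_backward <- function(net, dY, ch) {
  B <- ch$dims[["B"]]; T <- ch$dims[["T"]]
  if (net$kind == "unet") return(.unet_backward(net, dY, ch))
  hb <- .backward_head(net, dY, ch$head)
  grads <- hb$grads
  d <- dropout_backward(hb$dz, ch$drop2)
  if (net$kind == "dual" && net$metadata_dim > 0) {
    fw <- net$cfg$feature_fc_width
    zc <- ncol(d)
    fd <- rowsum(d[, zc - fw + seq_len(fw), drop = FALSE],
                 rep(seq_len(B), T))
    for (l in rev(seq_len(net$cfg$feature_fc_layers))) {
      fd <- relu_backward(fd, ch$feat[[paste0("frelu", l)]])
      fb <- dense_backward(fd, ch$feat[[paste0("feat", l)]],
                           net$params[[paste0("feat", l, "_W")]])
      grads[[paste0("feat", l, "_W")]] <- fb$dW
      grads[[paste0("feat", l, "_b")]] <- fb$db
      fd <- fb$dx
    }
    d <- d[, seq_len(zc - fw), drop = FALSE]
  }
  bb <- .backward_backbone(net, d, ch$backbone, B)
  acc_grads(grads, bb$grads)
}

# ---- U-Net forward / backward ---------------------------------------------

.unet_forward <- function(net, X, M, dropout_active, cache, raw = FALSE) {
  cfg <- net$cfg; p <- net$params; K <- cfg$kernel_size
  B <- nrow(X); T <- ncol(X)
  xs <- matrix(as.vector(X), ncol = 1)
  if (net$metadata_dim > 0)
    xs <- cbind(xs, M[rep(seq_len(B), T), , drop = FALSE])
  ch <- list(dims = c(B = B, T = T))
  cr <- function(a, nm) {
    cv <- conv1d_forward(a, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                         K, B)
    rl <- relu_forward(cv$out)
    ch[[paste0(nm, "_c")]] <<- cv$cache
    ch[[paste0(nm, "_r")]] <<- rl$cache
    rl$out
  }
  e1 <- cr(xs, "e1"); p1 <- maxpool1d_forward(e1, B); ch$p1 <- p1$cache
  e2 <- cr(p1$out, "e2"); p2 <- maxpool1d_forward(e2, B); ch$p2 <- p2$cache
  e3 <- cr(p2$out, "e3"); p3 <- maxpool1d_forward(e3, B); ch$p3 <- p3$cache
  mid <- cr(p3$out, "mid")
  dr <- dropout_forward(mid, cfg$dropout_rate, dropout_active)
  ch$dropm <- dr$cache
  d3 <- cr(cbind(upsample1d_forward(dr$out, B), e3), "d3")
  d2 <- cr(cbind(upsample1d_forward(d3, B), e2), "d2")
  d1 <- cr(cbind(upsample1d_forward(d2, B), e1), "d1")
  ov <- conv1d_forward(d1, p$out_W, p$out_b, 1L, B)
  ch$out_c <- ov$cache
  list(Y = if (raw) ov$out else .seqmat_to_array(ov$out, B, T),
       cache = if (cache) ch)
}

.unet_backward <- function(net, dY, ch) {
  p <- net$params; K <- net$cfg$kernel_size
  B <- ch$dims[["B"]]
  bf <- net$base_filters
  cw <- c(bf, 2L * bf, 4L * bf)                     # encoder channel widths
  grads <- list()
  crb <- function(d, nm) {
    d <- relu_backward(d, ch[[paste0(nm, "_r")]])
    cb <- conv1d_backward(d, ch[[paste0(nm, "_c")]], p[[paste0(nm, "_W")]],
                          K, B)
    grads[[paste0(nm, "_W")]] <<- cb$dW
    grads[[paste0(nm, "_b")]] <<- cb$db
    cb$dx
  }
  sp <- function(d, n_up) {
    list(up = d[, seq_len(n_up), drop = FALSE],
         skip = d[, n_up + seq_len(ncol(d) - n_up), drop = FALSE])
  }
  cb <- conv1d_backward(dY, ch$out_c, p$out_W, 1L, B)  # linear output conv
  grads$out_W <- cb$dW; grads$out_b <- cb$db
  s1 <- sp(crb(cb$dx, "d1"), cw[1])                 # cat1 = [up(d2), e1]
  s2 <- sp(crb(upsample1d_backward(s1$up, B), "d2"), cw[2])  # [up(d3), e2]
  s3 <- sp(crb(upsample1d_backward(s2$up, B), "d3"), cw[3])  # [up(mid'), e3]
  d_mid <- dropout_backward(upsample1d_backward(s3$up, B), ch$dropm)
  d_p3 <- crb(d_mid, "mid")
  d_e3 <- maxpool1d_backward(d_p3, ch$p3, B) + s3$skip
  d_p2 <- crb(d_e3, "e3")
  d_e2 <- maxpool1d_backward(d_p2, ch$p2, B) + s2$skip
  d_p1 <- crb(d_e2, "e2")
  d_e1 <- maxpool1d_backward(d_p1, ch$p1, B) + s1$skip
  crb(d_e1, "e1")
  grads
}
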