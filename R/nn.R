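# Minimal dense/convolutional/recurrent network engine.
#
# Sequence batches use a flat "seqmat" layout: a (B*T) x C matrix whose row
# b + (t-1)*B holds the C channel values of batch item b at time step t.
# This keeps every layer a plain matrix operation (convolution becomes a
# row-gathered GEMM, channel concatenation becomes cbind) and maps directly
# onto the compiled LSTM kernels.  Layers return list(out, cache) forward
# and gradients backward so the training loop stays generic.

glorot_init <- function(nin, nout, rng_fun = stats::runif) {
  lim <- sqrt(6 / (nin + nout))
  matrix(rng_fun(nin * nout, -lim, lim), nin, nout)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

# ---- dense -----------------------------------------------------------------

dense_forward <- function(x, W, b) {
  out <- x %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, cache = x)
}

dense_backward <- function(dout, cache, W) {
  list(dx = dout %*% t(W),
       dW = crossprod(cache, dout),
       db = colSums(dout))
}

# ---- 1-D convolution on seqmat (same padding, stride 1) --------------------

# row gather indices: for kernel tap k, destination times with a valid
# source time t + (k - 1 - pad); returns NULL when no rows are valid
.conv_tap_rows <- function(k, pad, B, T) {
  o <- k - 1L - pad
  src <- seq_len(T) + o
  ok <- which(src >= 1L & src <= T)
  if (!length(ok)) return(NULL)
  list(dst = rep((ok - 1L) * B, each = B) + seq_len(B),
       src = rep((src[ok] - 1L) * B, each = B) + seq_len(B))
}

# W is (C_in * K) x C_out with column block (k-1)*C + (1:C); b length C_out
conv1d_forward <- function(x, W, b, K, B) {
  C <- ncol(x); T <- nrow(x) %/% B
  pad <- (K - 1L) %/% 2L
  P <- matrix(0, nrow(x), C * K)
  for (k in seq_len(K)) {
    rw <- .conv_tap_rows(k, pad, B, T)
    if (!is.null(rw))
      P[rw$dst, (k - 1L) * C + seq_len(C)] <- x[rw$src, , drop = FALSE]
  }
  Y <- sweep(P %*% W, 2, b, "+")
  list(out = Y, cache = list(P = P, C = C, T = T))
}

conv1d_backward <- function(dout, cache, W, K, B) {
  C <- cache$C; T <- cache$T
  pad <- (K - 1L) %/% 2L
  dW <- crossprod(cache$P, dout)
  db <- colSums(dout)
  dP <- dout %*% t(W)
  dx <- matrix(0, nrow(dout), C)
  for (k in seq_len(K)) {
    rw <- .conv_tap_rows(k, pad, B, T)
    if (!is.null(rw))
      dx[rw$src, ] <- dx[rw$src, , drop = FALSE] +
        dP[rw$dst, (k - 1L) * C + seq_len(C), drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- dropout (inverted) ----------------------------------------------------

dropout_forward <- function(x, rate, active) {
  if (!active || rate <= 0) return(list(out = x, cache = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# ---- max pooling / nearest upsampling along time (factor 2) ----------------

.pool_rows <- function(B, T) {
  list(odd = rep((seq(1L, T, 2L) - 1L) * B, each = B) + seq_len(B),
       even = rep((seq(2L, T, 2L) - 1L) * B, each = B) + seq_len(B))
}

maxpool1d_forward <- function(x, B) {
  T <- nrow(x) %/% B
  rw <- .pool_rows(B, T)
  a <- x[rw$odd, , drop = FALSE]; b <- x[rw$even, , drop = FALSE]
  take_a <- a >= b
  out <- a
  out[!take_a] <- b[!take_a]
  list(out = out, cache = list(take_a = take_a, T = T))
}

maxpool1d_backward <- function(dout, cache, B) {
  rw <- .pool_rows(B, cache$T)
  dx <- matrix(0, cache$T * B, ncol(dout))
  dx[rw$odd, ] <- dout * cache$take_a
  dx[rw$even, ] <- dout * !cache$take_a
  dx
}

upsample1d_forward <- function(x, B) {
  T <- nrow(x) %/% B
  rw <- .pool_rows(B, 2L * T)
  out <- matrix(0, 2L * nrow(x), ncol(x))
  out[rw$odd, ] <- x
  out[rw$even, ] <- x
  out
}

upsample1d_backward <- function(dout, B) {
  T2 <- nrow(dout) %/% (2L * B)
  rw <- .pool_rows(B, 2L * T2)
  dout[rw$odd, , drop = FALSE] + dout[rw$even, , drop = FALSE]
}

# ---- bidirectional LSTM ----------------------------------------------------

# params: Wx_f, Wh_f, b_f (forward-in-time), Wx_b, Wh_b, b_b (backward);
# output concatenates the two hidden sequences along channels.
bilstm_forward <- function(x, p, B, cache = TRUE) {
  fw <- lstm_sm_forward(x, p$Wx_f, p$Wh_f, p$b_f, B, FALSE, cache)
  bw <- lstm_sm_forward(x, p$Wx_b, p$Wh_b, p$b_b, B, TRUE, cache)
  list(out = cbind(fw$H, bw$H), cache = list(fw = fw, bw = bw, x = x))
}

bilstm_backward <- function(dout, cache, p, B) {
  H <- nrow(p$Wh_f)
  gf <- lstm_sm_backward(dout[, seq_len(H), drop = FALSE], cache$x,
                         p$Wx_f, p$Wh_f, cache$fw$H, cache$fw$C,
                         cache$fw$G, B, FALSE)
  gb <- lstm_sm_backward(dout[, H + seq_len(H), drop = FALSE], cache$x,
                         p$Wx_b, p$Wh_b, cache$bw$H, cache$bw$C,
                         cache$bw$G, B, TRUE)
  list(dx = gf$dX + gb$dX,
       grads = list(Wx_f = gf$dWx, Wh_f = gf$dWh, b_f = as.numeric(gf$db),
                    Wx_b = gb$dWx, Wh_b = gb$dWh, b_b = as.numeric(gb$db)))
}

bilstm_init <- function(nin, units) {
  # forget-gate bias 1 for stable early training
  b0 <- rep(0, 4L * units); b0[units + seq_len(units)] <- 1
  list(Wx_f = glorot_init(nin, 4L * units),
       Wh_f = glorot_init(units, 4L * units), b_f = b0,
       Wx_b = glorot_init(nin, 4L * units),
       Wh_b = glorot_init(units, 4L * units), b_b = b0)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else rep(0, length(p))
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# accumulate named gradient lists (sums matching names)
acc_grads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}
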