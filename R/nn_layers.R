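# Internal layer machinery for the ECA network.
#
# Activations are stored as dense matrices of shape (B*H*W, C): rows
# ordered sample-major, then height, then width; columns are channels.
# Convolutions are evaluated as im2col gathers followed by one BLAS
# matrix multiply; backward passes scatter through the same index maps
# (per-tap scatters are injective for stride >= 1, so plain indexed
# assignment accumulates correctly).  Weight matrices have shape
# (kh*kw*C_in, C_out) with rows ordered tap-fastest within input
# channel.

# Index map for a (possibly strided) 'same'-padded convolution.
# Returns list(idx, H2, W2, zero_row): idx is (B*H2*W2, kh*kw) of row
# indices into the activation matrix extended by one trailing zero row.
.conv_index <- function(B, H, W, kh, kw, sh = 1, sw = 1) {
  H2 <- ceiling(H / sh); W2 <- ceiling(W / sw)
  pad_h <- max((H2 - 1) * sh + kh - H, 0)
  pad_w <- max((W2 - 1) * sw + kw - W, 0)
  top <- pad_h %/% 2; left <- pad_w %/% 2
  hh <- rep(seq_len(H2), each = W2)      # output rows ordered h-major, w fastest
  ww <- rep(seq_len(W2), times = H2)
  K <- kh * kw
  base <- matrix(NA_integer_, H2 * W2, K)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    hin <- (hh - 1) * sh + i - top
    win <- (ww - 1) * sw + j - left
    ok <- hin >= 1 & hin <= H & win >= 1 & win <= W
    v <- (hin - 1) * W + win
    v[!ok] <- NA_integer_
    base[, (i - 1) * kw + j] <- v
  }
  zero_row <- B * H * W + 1L
  n_out <- H2 * W2
  idx <- base[rep(seq_len(n_out), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * H * W, each = n_out)
  idx[is.na(idx)] <- zero_row
  storage.mode(idx) <- "integer"
  list(idx = idx, H2 = H2, W2 = W2, zero_row = zero_row, K = K)
}

# Index map for non-overlapping max pooling; requires exact division.
.pool_index <- function(B, H, W, ph, pw) {
  if (H %% ph || W %% pw)
    stop("pooling window (", ph, "x", pw, ") does not divide the ",
         H, "x", W, " map")
  H2 <- H %/% ph; W2 <- W %/% pw
  hh <- rep(seq_len(H2), each = W2)
  ww <- rep(seq_len(W2), times = H2)
  K <- ph * pw
  base <- matrix(0L, H2 * W2, K)
  for (i in seq_len(ph)) for (j in seq_len(pw))
    base[, (i - 1) * pw + j] <- ((hh - 1) * ph + i - 1) * W + (ww - 1) * pw + j
  n_out <- H2 * W2
  idx <- base[rep(seq_len(n_out), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * H * W, each = n_out)
  storage.mode(idx) <- "integer"
  list(idx = idx, H2 = H2, W2 = W2, K = K)
}

.conv_fwd <- function(X, map, Wt, bias) {
  r <- cpp_conv_fwd(X, map$idx, Wt, bias)
  list(Y = r$Y, X_col = r$Xcol, n_in = nrow(X), C_in = ncol(X))
}

.conv_bwd <- function(dY, fwd, map, Wt) {
  r <- cpp_conv_bwd(dY, fwd$X_col, map$idx, Wt, fwd$n_in)
  list(dX = r$dX, dW = r$dW, db = as.vector(r$db))
}

.pool_fwd <- function(X, map) {
  r <- cpp_pool_fwd(X, map$idx)
  list(Y = r$Y, arg = r$arg, n_in = nrow(X))
}

.pool_bwd <- function(dY, fwd, map) {
  cpp_pool_bwd(dY, fwd$arg, map$idx, fwd$n_in)
}

# Fused batch-normalization + ReLU wrappers.  The backward pass
# re-centers the cached pre-BN activation X with the batch mean instead
# of storing a centered copy.
.bnrelu_fwd <- function(X, gamma, beta, state, train, momentum = 0.1,
                        eps = 1e-5) {
  r <- cpp_bnrelu_fwd(X, gamma, beta, state$mean, state$var, train,
                      momentum, eps)
  if (train) {
    state$mean <- as.vector(r$mean)
    state$var <- as.vector(r$var)
  }
  list(A = r$A, bmean = r$bmean, inv_sd = r$inv_sd, state = state)
}

.bnrelu_bwd <- function(dA, A, X, fwd, gamma) {
  r <- cpp_bnrelu_bwd(dA, A, X, fwd$bmean, fwd$inv_sd, gamma)
  list(dX = r$dX, dgamma = as.vector(r$dgamma), dbeta = as.vector(r$dbeta))
}

# Shift matrix columns by s (positive: take from higher indices),
# zero-filling out-of-range columns.
.shift_cols <- function(M, s) {
  C <- ncol(M)
  out <- matrix(0, nrow(M), C)
  if (s >= 0) {
    if (s < C) out[, seq_len(C - s)] <- M[, (s + 1):C, drop = FALSE]
  } else {
    if (-s < C) out[, (1 - s):C] <- M[, seq_len(C + s), drop = FALSE]
  }
  out
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# Cross-channel 1-D convolution of pooled channel descriptors.
# y: (B, C) matrix; kernel: odd-length weights; zero-padded ends.
.eca_conv <- function(y, kernel) {
  k <- length(kernel)
  hk <- (k - 1L) %/% 2L
  z <- matrix(0, nrow(y), ncol(y))
  for (j in seq_len(k)) z <- z + kernel[j] * .shift_cols(y, j - 1L - hk)
  z
}

.eca_conv_bwd <- function(dz, y, kernel) {
  k <- length(kernel)
  hk <- (k - 1L) %/% 2L
  dy <- matrix(0, nrow(y), ncol(y))
  dkernel <- numeric(k)
  for (j in seq_len(k)) {
    dy <- dy + kernel[j] * .shift_cols(dz, -(j - 1L - hk))
    dkernel[j] <- sum(dz * .shift_cols(y, j - 1L - hk))
  }
  list(dy = dy, dkernel = dkernel)
}

# Numerically stable softmax cross-entropy.
# logits: (B, n_classes); y: 1-based labels.
.softmax_ce <- function(logits, y) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  B <- nrow(logits)
  picked <- p[cbind(seq_len(B), y)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dlogits <- p
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  list(loss = loss, prob = p, dlogits = dlogits / B)
}
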