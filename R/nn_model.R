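#' Adaptive ECA kernel size from the channel count
#'
#' Computes the cross-channel neighborhood size
#' `k = | log2(C)/gamma + b/gamma |_odd` - the nearest odd integer, with
#' ties rounded up and a floor of 1.  With the defaults (gamma = 2,
#' b = 1) a 64-channel map gives k = 3.
#'
#' @param C Channel count (positive integer).
#' @param gamma,b Fitting factors of the mapping.
#' @return Odd integer kernel size.
#' @examples
#' adaptive_kernel_size(64)   # 3
#' adaptive_kernel_size(256)  # 5
#' @export
adaptive_kernel_size <- function(C, gamma = 2, b = 1) {
  if (C < 1 || C != round(C)) stop("C must be a positive integer")
  if (gamma <= 0) stop("gamma must be positive")
  t <- log2(C) / gamma + b / gamma
  lower <- 2 * floor((t - 1) / 2) + 1
  k <- if (t - lower < (lower + 2) - t) lower else lower + 2
  max(as.integer(k), 1L)
}

#' Network configuration for the ECA classifier
#'
#' Describes the fixed pipeline: Conv1 (1-D, 32 filters) whose outputs
#' are stacked into a single-channel 2-D feature map, a 2x2 max pool,
#' Conv2 and Conv3 (3x3, stride 2, 32 channels, batch-normalized), a 2x2
#' max pool after Conv2, Conv4 (1x1, 64 channels), the ECA attention
#' module (skipped for the plain-CNN ablation), a final 3x2 max pool,
#' and dense layers 256 -> 128 -> `n_classes` with softmax.
#'
#' @param n_classes Number of classes.
#' @param input_length Spectrum length (240 for the standard band).
#' @param input_channels 2 for the hybrid spectrum, 1 for the
#'   single-metric ablations.
#' @param conv1_filters,conv1_kernel Input-block 1-D convolution.
#' @param conv23_channels Channels of Conv2/Conv3.
#' @param conv4_channels Channels of the 1x1 Conv4 (feeds ECA).
#' @param fc_sizes Sizes of the two fully connected layers.
#' @param eca_gamma,eca_b Adaptive-kernel factors, see
#'   [adaptive_kernel_size()].
#' @param use_eca Include the ECA module (`FALSE` = plain CNN).
#' @return Object of class `thz_netconfig`.
#' @export
network_config <- function(n_classes = 20, input_length = 240,
                           input_channels = 2, conv1_filters = 32,
                           conv1_kernel = 7, conv23_channels = 32,
                           conv4_channels = 64, fc_sizes = c(256, 128),
                           eca_gamma = 2, eca_b = 1, use_eca = TRUE) {
  if (conv4_channels < 2) stop("conv4_channels must be >= 2")
  if (any(fc_sizes < 1)) stop("fc sizes must be positive")
  if (eca_gamma <= 0) stop("eca_gamma must be positive")
  structure(list(n_classes = n_classes, input_length = input_length,
                 input_channels = input_channels,
                 conv1_filters = conv1_filters, conv1_kernel = conv1_kernel,
                 conv23_channels = conv23_channels,
                 conv4_channels = conv4_channels, fc_sizes = fc_sizes,
                 eca_gamma = eca_gamma, eca_b = eca_b, use_eca = use_eca),
            class = "thz_netconfig")
}

# Spatial geometry of every stage, computed once from the config.
.net_geometry <- function(cfg) {
  H0 <- cfg$input_length; W0 <- cfg$conv1_filters
  if (H0 %% 2 || W0 %% 2) stop("input length and filter count must be even")
  H1 <- H0 %/% 2; W1 <- W0 %/% 2                 # pool (2,2) on the map
  H2 <- ceiling(H1 / 2); W2 <- ceiling(W1 / 2)   # conv2 stride 2
  if (H2 %% 2 || W2 %% 2) stop("input length incompatible with pooling")
  H2p <- H2 %/% 2; W2p <- W2 %/% 2               # pool (2,2)
  H3 <- ceiling(H2p / 2); W3 <- ceiling(W2p / 2) # conv3 stride 2
  if (H3 %% 3 || W3 %% 2)
    stop("input length incompatible with the final 3x2 pooling")
  H4 <- H3 %/% 3; W4 <- W3 %/% 2                 # pool (3,2)
  list(H0 = H0, W0 = W0, H1 = H1, W1 = W1, H2 = H2, W2 = W2,
       H2p = H2p, W2p = W2p, H3 = H3, W3 = W3, H4 = H4, W4 = W4,
       flat = H4 * W4 * cfg$conv4_channels)
}

.he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build the ECA network
#'
#' Initializes all parameters (He-scaled random weights, unit batch-norm
#' scales) under the given seed and returns an untrained model.  The ECA
#' cross-channel kernel size is derived from the Conv4 channel count via
#' [adaptive_kernel_size()].
#'
#' @param cfg A [network_config()].
#' @param seed Initialization seed.
#' @return Object of class `thz_ecanet`.
#' @export
build_network <- function(cfg = network_config(), seed = 1) {
  stopifnot(inherits(cfg, "thz_netconfig"))
  geo <- .net_geometry(cfg)
  set.seed(seed)
  k1 <- cfg$conv1_kernel * cfg$input_channels
  C23 <- cfg$conv23_channels
  p <- list(
    W1 = .he_init(k1, cfg$conv1_filters, k1), b1 = numeric(cfg$conv1_filters),
    g1 = rep(1, cfg$conv1_filters), be1 = numeric(cfg$conv1_filters),
    W2 = .he_init(9, C23, 9), b2 = numeric(C23),
    g2 = rep(1, C23), be2 = numeric(C23),
    W3 = .he_init(9 * C23, C23, 9 * C23), b3 = numeric(C23),
    g3 = rep(1, C23), be3 = numeric(C23),
    W4 = .he_init(C23, cfg$conv4_channels, C23),
    b4 = numeric(cfg$conv4_channels),
    g4 = rep(1, cfg$conv4_channels), be4 = numeric(cfg$conv4_channels),
    Wf1 = .he_init(geo$flat, cfg$fc_sizes[1], geo$flat),
    bf1 = numeric(cfg$fc_sizes[1]),
    Wf2 = .he_init(cfg$fc_sizes[1], cfg$fc_sizes[2], cfg$fc_sizes[1]),
    bf2 = numeric(cfg$fc_sizes[2]),
    Wf3 = .he_init(cfg$fc_sizes[2], cfg$n_classes, cfg$fc_sizes[2]),
    bf3 = numeric(cfg$n_classes)
  )
  eca_k <- NULL
  if (cfg$use_eca) {
    eca_k <- as.integer(min(adaptive_kernel_size(cfg$conv4_channels,
                                                 cfg$eca_gamma, cfg$eca_b),
                            cfg$conv4_channels))
    p$Weca <- stats::rnorm(eca_k, sd = 0.1)
  }
  bn0 <- function(C) list(mean = numeric(C), var = rep(1, C))
  structure(list(cfg = cfg, geo = geo, params = p, eca_k = eca_k,
                 bn = list(bn1 = bn0(cfg$conv1_filters), bn2 = bn0(C23),
                           bn3 = bn0(C23), bn4 = bn0(cfg$conv4_channels)),
                 seed = seed, trained = FALSE),
            class = "thz_ecanet")
}

#' @export
print.thz_ecanet <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<thz_ecanet>", if (x$cfg$use_eca) "ECA network" else "plain CNN",
      "-", np, "parameters,",
      x$cfg$input_length, "x", x$cfg$input_channels, "input,",
      x$cfg$n_classes, "classes",
      if (x$cfg$use_eca) paste0("(ECA k = ", x$eca_k, ")"), "\n")
  invisible(x)
}

# Index maps depend only on the geometry and the batch size; cache them
# in a package-local environment so repeated batches reuse them.
.maps_cache <- new.env(parent = emptyenv())

.net_maps <- function(model, B) {
  cfg <- model$cfg; geo <- model$geo
  key <- paste(geo$H0, geo$W0, cfg$conv1_kernel, B, sep = "_")
  maps <- .maps_cache[[key]]
  if (is.null(maps)) {
    maps <- list(
      B = B,
      conv1 = .conv_index(B, geo$H0, 1, cfg$conv1_kernel, 1),
      pool0 = .pool_index(B, geo$H0, geo$W0, 2, 2),
      conv2 = .conv_index(B, geo$H1, geo$W1, 3, 3, 2, 2),
      pool2 = .pool_index(B, geo$H2, geo$W2, 2, 2),
      conv3 = .conv_index(B, geo$H2p, geo$W2p, 3, 3, 2, 2),
      pool3 = .pool_index(B, geo$H3, geo$W3, 3, 2)
    )
    .maps_cache[[key]] <- maps
  }
  maps
}

# Input array (B, L, C) -> activation matrix (B*L, C), rows sample-major.
.input_to_rows <- function(x) {
  B <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
  matrix(aperm(x, c(2, 1, 3)), B * L, C)
}

# Full forward pass.  Returns logits and, when `keep = TRUE`, every
# intermediate needed by the backward pass.
.net_forward <- function(model, x, train = FALSE, keep = FALSE) {
  cfg <- model$cfg; geo <- model$geo; p <- model$params
  B <- dim(x)[1]
  maps <- .net_maps(model, B)
  cc <- list(maps = maps, B = B)

  X0 <- .input_to_rows(x)                                  # (B*240, C_in)
  c1 <- .conv_fwd(X0, maps$conv1, p$W1, p$b1)
  bn1 <- .bnrelu_fwd(c1$Y, p$g1, p$be1, model$bn$bn1, train)
  A1 <- bn1$A                                              # input block out
  M0 <- matrix(as.vector(t(A1)), ncol = 1)                 # 2-D map, 1 chan
  pl0 <- .pool_fwd(M0, maps$pool0)
  c2 <- .conv_fwd(pl0$Y, maps$conv2, p$W2, p$b2)
  bn2 <- .bnrelu_fwd(c2$Y, p$g2, p$be2, model$bn$bn2, train)
  A2 <- bn2$A
  pl2 <- .pool_fwd(A2, maps$pool2)
  c3 <- .conv_fwd(pl2$Y, maps$conv3, p$W3, p$b3)
  bn3 <- .bnrelu_fwd(c3$Y, p$g3, p$be3, model$bn$bn3, train)
  A3 <- bn3$A
  c4 <- list(Y = A3 %*% p$W4 + rep(p$b4, each = nrow(A3)))  # 1x1 conv
  bn4 <- .bnrelu_fwd(c4$Y, p$g4, p$be4, model$bn$bn4, train)
  A4 <- bn4$A

  if (cfg$use_eca) {
    hw <- geo$H3 * geo$W3
    grp <- rep(seq_len(B), each = hw)
    y_pool <- rowsum(A4, grp, reorder = FALSE) / hw          # (B, C4)
    z <- .eca_conv(y_pool, p$Weca)
    s <- .sigmoid(z)
    s_rows <- s[grp, , drop = FALSE]
    A5 <- A4 * s_rows
  } else {
    A5 <- A4
  }

  pl3 <- .pool_fwd(A5, maps$pool3)
  flat <- matrix(aperm(array(pl3$Y, c(geo$H4 * geo$W4, B,
                                      cfg$conv4_channels)),
                       c(2, 1, 3)), B, geo$flat)
  F1 <- flat %*% p$Wf1 + rep(p$bf1, each = B)
  A6 <- pmax(F1, 0)
  F2 <- A6 %*% p$Wf2 + rep(p$bf2, each = B)
  A7 <- pmax(F2, 0)
  logits <- A7 %*% p$Wf3 + rep(p$bf3, each = B)

  if (train) {
    model$bn$bn1 <- bn1$state; model$bn$bn2 <- bn2$state
    model$bn$bn3 <- bn3$state; model$bn$bn4 <- bn4$state
  }
  if (keep)
    cc <- c(cc, list(X0 = X0, c1 = c1, bn1 = bn1, A1 = A1, pl0 = pl0,
                     c2 = c2, bn2 = bn2, A2 = A2, pl2 = pl2, c3 = c3,
                     bn3 = bn3, A3 = A3, c4 = c4, bn4 = bn4, A4 = A4,
                     eca = if (cfg$use_eca)
                       list(y_pool = y_pool, s = s, s_rows = s_rows,
                            grp = grp, hw = hw),
                     A5 = A5, pl3 = pl3, flat = flat, A6 = A6, A7 = A7))
  list(logits = logits, model = model, cache = cc)
}

# Backward pass; returns gradients named like the parameters.
.net_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg; geo <- model$geo; p <- model$params
  cc <- cache; maps <- cc$maps; B <- cc$B
  g <- list()

  g$Wf3 <- crossprod(cc$A7, dlogits); g$bf3 <- colSums(dlogits)
  dA7 <- dlogits %*% t(p$Wf3); dF2 <- dA7 * (cc$A7 > 0)
  g$Wf2 <- crossprod(cc$A6, dF2); g$bf2 <- colSums(dF2)
  dA6 <- dF2 %*% t(p$Wf2); dF1 <- dA6 * (cc$A6 > 0)
  g$Wf1 <- crossprod(cc$flat, dF1); g$bf1 <- colSums(dF1)
  dflat <- dF1 %*% t(p$Wf1)

  dpl3 <- matrix(aperm(array(dflat, c(B, geo$H4 * geo$W4,
                                      cfg$conv4_channels)),
                       c(2, 1, 3)), B * geo$H4 * geo$W4, cfg$conv4_channels)
  dA5 <- .pool_bwd(dpl3, cc$pl3, maps$pool3)

  if (cfg$use_eca) {
    e <- cc$eca
    dA4 <- dA5 * e$s_rows
    ds <- rowsum(dA5 * cc$A4, e$grp, reorder = FALSE)
    dz <- ds * e$s * (1 - e$s)
    eb <- .eca_conv_bwd(dz, e$y_pool, p$Weca)
    g$Weca <- eb$dkernel
    dA4 <- dA4 + eb$dy[e$grp, , drop = FALSE] / e$hw
  } else {
    dA4 <- dA5
  }

  b4 <- .bnrelu_bwd(dA4, cc$A4, cc$c4$Y, cc$bn4, p$g4)
  g$g4 <- b4$dgamma; g$be4 <- b4$dbeta
  g$W4 <- crossprod(cc$A3, b4$dX); g$b4 <- colSums(b4$dX)
  dA3 <- b4$dX %*% t(p$W4)

  b3 <- .bnrelu_bwd(dA3, cc$A3, cc$c3$Y, cc$bn3, p$g3)
  g$g3 <- b3$dgamma; g$be3 <- b3$dbeta
  cb3 <- .conv_bwd(b3$dX, cc$c3, maps$conv3, p$W3)
  g$W3 <- cb3$dW; g$b3 <- cb3$db
  dpl2 <- cb3$dX
  dA2 <- .pool_bwd(dpl2, cc$pl2, maps$pool2)

  b2 <- .bnrelu_bwd(dA2, cc$A2, cc$c2$Y, cc$bn2, p$g2)
  g$g2 <- b2$dgamma; g$be2 <- b2$dbeta
  cb2 <- .conv_bwd(b2$dX, cc$c2, maps$conv2, p$W2)
  g$W2 <- cb2$dW; g$b2 <- cb2$db
  dM0 <- .pool_bwd(cb2$dX, cc$pl0, maps$pool0)

  dA1 <- t(matrix(as.vector(dM0), geo$W0, B * geo$H0))
  b1 <- .bnrelu_bwd(dA1, cc$A1, cc$c1$Y, cc$bn1, p$g1)
  g$g1 <- b1$dgamma; g$be1 <- b1$dbeta
  cb1 <- .conv_bwd(b1$dX, cc$c1, maps$conv1, p$W1)
  g$W1 <- cb1$dW; g$b1 <- cb1$db
  g
}

#' Training configuration
#'
#' Defaults follow the full training protocol: SGD with Nesterov
#' momentum 0.9, initial learning rate 1e-3 decayed per update by
#' `lr / (1 + decay * iter)` with decay 1e-5, batch size 128, up to 300
#' epochs with early stopping after 30 epochs of non-decreasing
#' validation loss, then 100 fine-tuning epochs at 1e-4.
#'
#' @param epochs,fine_tune_epochs Epoch budgets of the two phases.
#' @param lr,fine_tune_lr Initial learning rates of the two phases.
#' @param lr_decay Per-update decay factor.
#' @param momentum Momentum coefficient.
#' @param nesterov Use Nesterov accelerated gradient.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience (epochs of non-decreasing
#'   validation loss).
#' @return Object of class `thz_trainconfig`.
#' @export
training_config <- function(epochs = 300, fine_tune_epochs = 100, lr = 1e-3,
                            fine_tune_lr = 1e-4, lr_decay = 1e-5,
                            momentum = 0.9, nesterov = TRUE,
                            batch_size = 128, patience = 30) {
  structure(list(epochs = epochs, fine_tune_epochs = fine_tune_epochs,
                 lr = lr, fine_tune_lr = fine_tune_lr, lr_decay = lr_decay,
                 momentum = momentum, nesterov = nesterov,
                 batch_size = batch_size, patience = patience),
            class = "thz_trainconfig")
}

#' Train the ECA network
#'
#' Mini-batch SGD with Nesterov momentum and cross-entropy loss, in two
#' phases (initial and fine-tuning learning rates), with early stopping
#' on the validation loss.  Fully deterministic under the seed.
#'
#' @param model A `thz_ecanet` from [build_network()].
#' @param train_set,val_set Splits from [assemble_datasets()]: lists
#'   with `x` (items x length x channels) and `y` (1-based labels).
#' @param tcfg A [training_config()].
#' @param seed Shuffling seed.
#' @param verbose Print per-epoch progress.
#' @return List with the trained `model` and `history` (data frame with
#'   per-epoch phase, losses and accuracies).
#' @export
nn_train <- function(model, train_set, val_set, tcfg = training_config(),
                     seed = 1, verbose = FALSE) {
  stopifnot(inherits(model, "thz_ecanet"))
  n <- dim(train_set$x)[1]
  if (n < 1 || length(val_set$y) < 1) stop("empty split")
  bs <- tcfg$batch_size
  if (bs > n) {
    warning("batch size ", bs, " larger than training set (", n,
            "); reduced")
    bs <- n
  }
  vel <- lapply(model$params, function(w) w * 0)
  history <- NULL
  set.seed(seed)

  run_phase <- function(model, vel, phase, epochs, lr0) {
    iter <- 0
    best_val <- Inf; stall <- 0
    hist <- NULL
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = bs)) {
        take <- ord[start:min(start + bs - 1, n)]
        xb <- train_set$x[take, , , drop = FALSE]
        yb <- train_set$y[take]
        fw <- .net_forward(model, xb, train = TRUE, keep = TRUE)
        model <- fw$model
        sm <- .softmax_ce(fw$logits, yb)
        g <- .net_backward(model, fw$cache, sm$dlogits)
        lr_t <- lr0 / (1 + tcfg$lr_decay * iter)
        for (nm in names(g)) {
          v_new <- tcfg$momentum * vel[[nm]] - lr_t * g[[nm]]
          vel[[nm]] <- v_new
          model$params[[nm]] <- model$params[[nm]] +
            (if (tcfg$nesterov) tcfg$momentum * v_new - lr_t * g[[nm]]
             else v_new)
        }
        iter <- iter + 1
        ep_loss <- ep_loss + sm$loss * length(take)
        ep_correct <- ep_correct +
          sum(max.col(sm$prob, ties.method = "first") == yb)
      }
      ev <- .net_eval(model, val_set$x, val_set$y)
      row <- data.frame(phase = phase, epoch = ep,
                        train_loss = ep_loss / n, train_acc = ep_correct / n,
                        val_loss = ev$loss, val_acc = ev$acc)
      hist <- rbind(hist, row)
      if (verbose)
        message(sprintf("[%s %3d] loss %.4f acc %.3f | val %.4f acc %.3f",
                        phase, ep, row$train_loss, row$train_acc,
                        row$val_loss, row$val_acc))
      if (ev$loss < best_val - 1e-9) { best_val <- ev$loss; stall <- 0 }
      else stall <- stall + 1
      if (stall >= tcfg$patience) break
    }
    list(model = model, vel = vel, hist = hist)
  }

  ph <- run_phase(model, vel, "initial", tcfg$epochs, tcfg$lr)
  model <- ph$model; vel <- ph$vel; history <- ph$hist
  if (tcfg$fine_tune_epochs > 0) {
    ph <- run_phase(model, vel, "fine_tune", tcfg$fine_tune_epochs,
                    tcfg$fine_tune_lr)
    model <- ph$model
    history <- rbind(history, ph$hist)
  }
  model$trained <- TRUE
  list(model = model, history = history)
}

.net_eval <- function(model, x, y, batch_size = 256) {
  pr <- predict(model, x, batch_size = batch_size)
  picked <- pr$prob[cbind(seq_along(y), y)]
  list(loss = -mean(log(pmax(picked, 1e-300))),
       acc = mean(pr$class == y))
}

#' Predict class probabilities and labels
#'
#' Forward passes in evaluation mode (batch-norm running statistics).
#' Ties in the argmax resolve to the lowest class index.
#'
#' @param object A `thz_ecanet`.
#' @param x Input array (items x length x channels) or a dataset split
#'   (list with an `x` element).
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return List with `prob` (items x classes) and `class` (1-based
#'   argmax labels).
#' @export
predict.thz_ecanet <- function(object, x, batch_size = 256, ...) {
  if (is.list(x) && !is.null(x$x)) x <- x$x
  if (length(dim(x)) == 2) x <- array(x, c(1, dim(x)))
  n <- dim(x)[1]
  if (n == 0)
    return(list(prob = matrix(0, 0, object$cfg$n_classes),
                class = integer(0)))
  if (dim(x)[2] != object$cfg$input_length ||
      dim(x)[3] != object$cfg$input_channels)
    stop("input shape (", dim(x)[2], " x ", dim(x)[3],
         ") does not match the network (", object$cfg$input_length, " x ",
         object$cfg$input_channels, ")")
  prob <- matrix(0, n, object$cfg$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1, n)
    fw <- .net_forward(object, x[take, , , drop = FALSE], train = FALSE)
    object <- fw$model
    m <- apply(fw$logits, 1, max)
    e <- exp(fw$logits - m)
    prob[take, ] <- e / rowSums(e)
  }
  list(prob = prob, class = max.col(prob, ties.method = "first"))
}

#' ECA attention state of a feature map
#'
#' Standalone version of the attention module: global average pooling of
#' each channel, a zero-padded 1-D convolution across channels with the
#' given kernel, and a sigmoid.
#'
#' @param feature_map Matrix (spatial positions x channels) or 3-D array
#'   (H x W x C).
#' @param kernel Odd-length numeric kernel of the cross-channel
#'   convolution; its length is the neighborhood size k.
#' @return Object of class `thz_attention`: list with `pooled` (per
#'   channel), `weights` (in (0,1)), and `k`.
#' @export
eca_attention <- function(feature_map, kernel) {
  k <- length(kernel)
  if (k %% 2 == 0) stop("kernel size k must be odd")
  fm <- .as_channel_matrix(feature_map)
  if (k > ncol(fm)) stop("kernel size exceeds the channel count")
  pooled <- colMeans(fm)
  z <- .eca_conv(matrix(pooled, 1), kernel)
  weights <- as.vector(.sigmoid(z))
  structure(list(pooled = pooled, weights = weights, k = k),
            class = "thz_attention")
}

#' Apply attention weights to a feature map
#'
#' Scales each channel by its attention weight; spatial dimensions are
#' unchanged.
#'
#' @param feature_map Matrix (spatial x channels) or array (H x W x C).
#' @param att A `thz_attention` from [eca_attention()].
#' @return Object of the same shape as `feature_map`.
#' @export
apply_attention <- function(feature_map, att) {
  stopifnot(inherits(att, "thz_attention"))
  if (is.matrix(feature_map)) {
    if (ncol(feature_map) != length(att$weights))
      stop("channel count mismatch")
    return(sweep(feature_map, 2, att$weights, `*`))
  }
  d <- dim(feature_map)
  if (length(d) != 3 || d[3] != length(att$weights))
    stop("channel count mismatch")
  sweep(feature_map, 3, att$weights, `*`)
}

.as_channel_matrix <- function(feature_map) {
  if (is.matrix(feature_map)) return(feature_map)
  d <- dim(feature_map)
  if (length(d) == 3) return(matrix(feature_map, d[1] * d[2], d[3]))
  stop("feature_map must be a matrix or a 3-D array")
}

#' Input-block feature map of one spectrum
#'
#' Returns the stacked Conv1 output (after batch normalization and ReLU,
#' in evaluation mode): the `input_length x conv1_filters` 2-D map that
#' the deeper convolutional layers consume - useful for inspecting what
#' the input block extracts from each metric.
#'
#' @param model A `thz_ecanet`.
#' @param item One spectrum: matrix (length x channels) or vector.
#' @return Matrix (input_length x conv1_filters).
#' @export
input_block_feature_map <- function(model, item) {
  stopifnot(inherits(model, "thz_ecanet"))
  if (is.vector(item)) item <- matrix(item, ncol = 1)
  x <- array(item, c(1, nrow(item), ncol(item)))
  X0 <- .input_to_rows(x)
  maps <- .conv_index(1, model$geo$H0, 1, model$cfg$conv1_kernel, 1)
  c1 <- .conv_fwd(X0, maps, model$params$W1, model$params$b1)
  bn1 <- .bnrelu_fwd(c1$Y, model$params$g1, model$params$be1,
                     model$bn$bn1, train = FALSE)
  bn1$A
}

#' Total number of trainable parameters
#' @param model A `thz_ecanet`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}
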