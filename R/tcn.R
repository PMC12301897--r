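# Temporal convolutional age regressor: dilated residual blocks (dilation
# 2^i, two valid-mode convolutions per block, ReLU), a per-timestep linear
# head and a sigmoid output in [0, 1]. Implemented directly (forward,
# backward, AdamW, cosine annealing) since no autodiff library is available;
# the same backward pass supplies input gradients for saliency analysis.
#
# Batch layout: a batch of B signals of length T with C channels is stored
# as a (B*T) x C matrix with row index b + (t-1)*B. Time steps are then
# contiguous row blocks, so a dilated convolution tap is a plain row-block
# shift followed by one matrix multiplication. Valid-mode start-aligned
# convolutions make the dense full-recording forward pass equal, timestep by
# timestep, to evaluating every sliding crop separately.

#' Model configuration for the temporal convolutional regressor
#'
#' @param n_blocks number of residual blocks; block `i` uses dilation
#'   `2^(i-1)` and two convolutions.
#' @param kernel_size taps per convolution.
#' @param n_filters feature channels per block.
#' @param dropout dropout probability on hidden activations in `[0, 1)`
#'   (training time only).
#' @return object of class `model_config` with the derived `receptive_field`
#'   (samples): `1 + 2 (kernel_size - 1) (2^n_blocks - 1)`.
#' @export
model_config <- function(n_blocks = 3, kernel_size = 5, n_filters = 32,
                         dropout = 0) {
  stopifnot(n_blocks >= 1, kernel_size >= 2, n_filters >= 1,
            dropout >= 0, dropout < 1)
  rf <- 1 + 2 * (kernel_size - 1) * (2^n_blocks - 1)
  structure(list(n_blocks = n_blocks, kernel_size = kernel_size,
                 n_filters = n_filters, dropout = dropout,
                 receptive_field = rf),
            class = "model_config")
}

#' Training configuration
#'
#' @param epochs training epochs (default 35).
#' @param batch_size crops per batch (default 128).
#' @param lr peak AdamW learning rate (cosine-annealed to 0).
#' @param weight_decay decoupled weight decay (applied to weights, not
#'   biases).
#' @param channel_dropout_p probability of zeroing each input channel of a
#'   training crop (augmentation; never applied at inference).
#' @param crops_per_recording random crops sampled per recording per epoch.
#' @param seed integer seed controlling initialization, crop sampling and
#'   dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 35, batch_size = 128, lr = 3e-3,
                         weight_decay = 1e-4, channel_dropout_p = 0.2,
                         crops_per_recording = 8, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, weight_decay >= 0,
            channel_dropout_p >= 0, channel_dropout_p < 1,
            crops_per_recording >= 1)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 weight_decay = weight_decay,
                 channel_dropout_p = channel_dropout_p,
                 crops_per_recording = crops_per_recording,
                 seed = as.integer(seed)),
            class = "train_config")
}

tcn_init <- function(cfg, n_channels) {
  he <- function(cin, cout, k)
    array(stats::rnorm(cin * cout * k, 0, sqrt(2 / (cin * k))),
          dim = c(cin, cout, k))
  blocks <- vector("list", cfg$n_blocks)
  cin <- n_channels
  for (i in seq_len(cfg$n_blocks)) {
    blk <- list(
      W1 = he(cin, cfg$n_filters, cfg$kernel_size),
      b1 = numeric(cfg$n_filters),
      W2 = he(cfg$n_filters, cfg$n_filters, cfg$kernel_size),
      b2 = numeric(cfg$n_filters),
      dilation = 2^(i - 1))
    if (cin != cfg$n_filters) {
      blk$Wp <- he(cin, cfg$n_filters, 1)[, , 1, drop = FALSE]
    }
    blocks[[i]] <- blk
    cin <- cfg$n_filters
  }
  structure(list(cfg = cfg, n_channels = n_channels, blocks = blocks,
                 head_w = stats::rnorm(cfg$n_filters, 0,
                                       sqrt(1 / cfg$n_filters)),
                 head_b = 0),
            class = "tcn_model")
}

#' @export
print.tcn_model <- function(x, ...) {
  cat(sprintf(
    "<tcn_model: %d blocks, kernel %d, %d filters, %d input channels, receptive field %d samples>\n",
    x$cfg$n_blocks, x$cfg$kernel_size, x$cfg$n_filters, x$n_channels,
    x$cfg$receptive_field))
  invisible(x)
}

# dilated valid convolution on the (B*T) x C layout
conv_fwd <- function(X, W, b, d, B) {
  k <- dim(W)[3]
  t_in <- nrow(X) / B
  t_out <- t_in - (k - 1) * d
  Y <- matrix(rep(b, each = B * t_out), B * t_out, length(b))
  for (j in seq_len(k)) {
    off <- (j - 1) * d * B
    Y <- Y + X[(off + 1):(off + B * t_out), , drop = FALSE] %*% W[, , j]
  }
  Y
}

conv_bwd <- function(dY, X, W, d, B) {
  k <- dim(W)[3]
  t_out <- nrow(dY) / B
  dW <- array(0, dim = dim(W))
  dX <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(k)) {
    off <- (j - 1) * d * B
    rows <- (off + 1):(off + B * t_out)
    dW[, , j] <- crossprod(X[rows, , drop = FALSE], dY)
    dX[rows, ] <- dX[rows, ] + dY %*% t(W[, , j])
  }
  list(dW = dW, db = colSums(dY), dX = dX)
}

tcn_forward <- function(model, X, B, train = FALSE) {
  cfg <- model$cfg
  cache <- list(inputs = list(), a1 = list(), h1 = list(), a2 = list(),
                res = list(), masks = list())
  H <- X
  for (i in seq_along(model$blocks)) {
    blk <- model$blocks[[i]]
    cache$inputs[[i]] <- H
    a1 <- conv_fwd(H, blk$W1, blk$b1, blk$dilation, B)
    h1 <- pmax(a1, 0)
    if (train && cfg$dropout > 0) {
      m1 <- matrix(stats::runif(length(h1)) >= cfg$dropout,
                   nrow(h1), ncol(h1)) / (1 - cfg$dropout)
      h1 <- h1 * m1
    } else m1 <- NULL
    a2 <- conv_fwd(h1, blk$W2, blk$b2, blk$dilation, B)
    t2 <- nrow(a2)
    res <- if (is.null(blk$Wp)) H[seq_len(t2), , drop = FALSE] else
      H[seq_len(t2), , drop = FALSE] %*% blk$Wp[, , 1]
    H2 <- pmax(a2 + res, 0)
    if (train && cfg$dropout > 0) {
      m2 <- matrix(stats::runif(length(H2)) >= cfg$dropout,
                   nrow(H2), ncol(H2)) / (1 - cfg$dropout)
      H2 <- H2 * m2
    } else m2 <- NULL
    cache$a1[[i]] <- a1; cache$h1[[i]] <- h1; cache$a2[[i]] <- a2
    cache$res[[i]] <- res; cache$masks[[i]] <- list(m1 = m1, m2 = m2)
    H <- H2
  }
  z <- drop(H %*% model$head_w) + model$head_b
  out <- 1 / (1 + exp(-z))
  list(out = out, z = z, H = H, cache = cache, B = B)
}

tcn_backward <- function(model, fwd, dout, want_input_grad = FALSE) {
  B <- fwd$B
  dz <- dout * fwd$out * (1 - fwd$out)
  grads <- list(head_w = drop(crossprod(fwd$H, dz)), head_b = sum(dz),
                blocks = vector("list", length(model$blocks)))
  dH <- outer(dz, model$head_w)
  for (i in rev(seq_along(model$blocks))) {
    blk <- model$blocks[[i]]
    ch <- fwd$cache
    m <- ch$masks[[i]]
    H_in <- ch$inputs[[i]]
    a2 <- ch$a2[[i]]; res <- ch$res[[i]]; h1 <- ch$h1[[i]]; a1 <- ch$a1[[i]]
    if (!is.null(m$m2)) dH <- dH * m$m2
    dpre <- dH * ((a2 + res) > 0)
    g2 <- conv_bwd(dpre, h1, blk$W2, blk$dilation, B)
    dres <- dpre
    dh1 <- g2$dX
    if (!is.null(m$m1)) dh1 <- dh1 * m$m1
    da1 <- dh1 * (a1 > 0)
    g1 <- conv_bwd(da1, H_in, blk$W1, blk$dilation, B)
    dH_in <- g1$dX
    t2 <- nrow(dpre)
    if (is.null(blk$Wp)) {
      dH_in[seq_len(t2), ] <- dH_in[seq_len(t2), ] + dres
      gWp <- NULL
    } else {
      dH_in[seq_len(t2), ] <- dH_in[seq_len(t2), ] +
        dres %*% t(blk$Wp[, , 1])
      gWp <- array(crossprod(H_in[seq_len(t2), , drop = FALSE], dres),
                   dim = dim(blk$Wp))
    }
    grads$blocks[[i]] <- list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW,
                              b2 = g2$db, Wp = gWp)
    dH <- dH_in
  }
  if (want_input_grad) grads$input <- dH
  grads
}

# flatten params/grads into aligned lists for the optimizer
tcn_param_refs <- function(model) {
  # paths are lists, never c(): an atomic path would coerce the block
  # index to character and silently address nothing
  refs <- list(list(list("head_w"), decay = TRUE),
               list(list("head_b"), decay = FALSE))
  for (i in seq_along(model$blocks)) {
    for (nm in c("W1", "W2", "Wp")) {
      if (!is.null(model$blocks[[i]][[nm]]))
        refs[[length(refs) + 1L]] <- list(list("blocks", i, nm), decay = TRUE)
    }
    for (nm in c("b1", "b2"))
      refs[[length(refs) + 1L]] <- list(list("blocks", i, nm), decay = FALSE)
  }
  refs
}

get_path <- function(x, path) {
  for (p in path) x <- x[[p]]
  x
}

set_path <- function(x, path, value) {
  if (length(path) == 1) {
    x[[path[[1]]]] <- value
    return(x)
  }
  x[[path[[1]]]] <- set_path(x[[path[[1]]]], path[-1], value)
  x
}

adamw_init <- function(model) {
  refs <- tcn_param_refs(model)
  list(refs = refs,
       m = lapply(refs, function(r) get_path(model, r[[1]]) * 0),
       v = lapply(refs, function(r) get_path(model, r[[1]]) * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adamw_step <- function(model, grads, opt, lr, weight_decay) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$refs)) {
    ref <- opt$refs[[i]]
    g <- get_path(grads, ref[[1]])
    p <- get_path(model, ref[[1]])
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
    upd <- (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    if (isTRUE(ref$decay)) p <- p - lr * weight_decay * p
    p <- p - lr * upd
    model <- set_path(model, ref[[1]], p)
  }
  list(model = model, opt = opt)
}

cosine_lr <- function(step, total_steps, lr0) {
  lr0 * 0.5 * (1 + cos(pi * (step - 1) / max(1, total_steps)))
}
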