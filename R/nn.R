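# Low-level building blocks of the 2D residual dilated convolutional
# network: im2col/col2im with dilation, batched forward/backward passes,
# Dice + cross-entropy loss and an Adam optimizer. Feature maps are stored
# as (batch*H*W) x channels matrices (images flattened column-major), so a
# convolution is one gather plus one matrix product and the heavy lifting
# goes through BLAS.

# index table for dilated 3x3 im2col on an H x W grid; 0 marks zero padding
.im2col_index <- function(H, W, d) {
  r <- rep.int(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  offs <- expand.grid(dy = c(-d, 0L, d), dx = c(-d, 0L, d))
  idx <- matrix(0L, H * W, 9L)
  for (o in seq_len(9L)) {
    rr <- r + offs$dy[o]; cj <- cc + offs$dx[o]
    ok <- rr >= 1L & rr <= H & cj >= 1L & cj <= W
    idx[ok, o] <- (cj[ok] - 1L) * H + rr[ok]
  }
  idx
}

# batch version: per-image offsets, still 0 for padding
.im2col_index_batch <- function(H, W, d, B, cache = NULL) {
  key <- sprintf("%d_%d_%d_%d", H, W, d, B)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  base <- .im2col_index(H, W, d)
  HW <- H * W
  idx <- matrix(0L, B * HW, 9L)
  for (b in seq_len(B)) {
    blk <- base
    blk[blk > 0L] <- blk[blk > 0L] + (b - 1L) * HW
    idx[((b - 1L) * HW + 1L):(b * HW), ] <- blk
  }
  if (!is.null(cache)) cache[[key]] <- idx
  idx
}

# X: (B*HW) x C_in -> cols: (B*HW) x (9*C_in); column (ch-1)*9 + o
.im2col <- function(X, ind) .im2col_cpp(X, ind)

# scatter-add transpose of .im2col; dcols: (B*HW) x (9*C)
.col2im <- function(dcols, ind, C) .col2im_cpp(dcols, ind, C)

.conv_forward <- function(cols, Wm, b) {
  Y <- cols %*% Wm
  Y + rep(b, each = nrow(Y))
}

# gradients from the cached forward im2col matrix
.conv_backward <- function(dY, cols, ind, Wm, C_in) {
  list(dW = crossprod(cols, dY),
       db = colSums(dY),
       dX = .col2im(dY %*% t(Wm), ind, C_in))
}

# channel-matching skip connection: zero-pad or truncate channels
.skip_forward <- function(X, c_out) {
  c_in <- ncol(X)
  if (c_in == c_out) return(X)
  if (c_in < c_out) return(cbind(X, matrix(0, nrow(X), c_out - c_in)))
  X[, seq_len(c_out), drop = FALSE]
}

.skip_backward <- function(dS, c_in) {
  c_out <- ncol(dS)
  if (c_in == c_out) return(dS)
  if (c_in < c_out) return(dS[, seq_len(c_in), drop = FALSE])
  cbind(dS, matrix(0, nrow(dS), c_in - c_out))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# full forward pass; keeps per-block inputs and activations for backprop
.net_forward <- function(model, X, B, keep_cache = FALSE) {
  cfg <- model$config
  S <- cfg$input_size
  cache <- if (keep_cache) list(blocks = vector("list", length(model$blocks))) else NULL
  A <- X
  for (bl in seq_along(model$blocks)) {
    blk <- model$blocks[[bl]]
    ind <- .im2col_index_batch(S, S, cfg$dilations[bl], B, model$idx_cache)
    cols1 <- .im2col(A, ind)
    Z1 <- .conv_forward(cols1, blk$W1, blk$b1)
    A1 <- pmax(Z1, 0)
    cols2 <- .im2col(A1, ind)
    Z2 <- .conv_forward(cols2, blk$W2, blk$b2)
    Ssum <- Z2 + .skip_forward(A, ncol(Z2))
    O <- pmax(Ssum, 0)
    if (keep_cache) {
      cache$blocks[[bl]] <- list(C_in = ncol(A), cols1 = cols1, A1 = A1,
                                 cols2 = cols2, O = O)
    }
    A <- O
  }
  logit <- A %*% model$head$W + rep(model$head$b, each = nrow(A))
  prob <- .sigmoid(logit)
  if (keep_cache) { cache$A_last <- A; cache$prob <- prob }
  list(prob = prob, cache = cache)
}

# gradient of the combined loss w.r.t. the logit; targets g in {0,1}
# bce: mean over all pixels; dice: soft Dice averaged over the batch images
.loss_and_dlogit <- function(prob, g, B, loss = "sum", eps = 1) {
  n <- length(prob)
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  l_bce <- -mean(g * log(p) + (1 - g) * log(1 - p))
  d_bce <- (prob - g) / n
  HW <- n / B
  dim(p) <- NULL
  pm <- matrix(prob, HW, B); gm <- matrix(g, HW, B)
  inter <- colSums(pm * gm); tot <- colSums(pm) + colSums(gm)
  dvals <- (2 * inter + eps) / (tot + eps)
  l_dice <- 1 - mean(dvals)
  # d(1 - D_b)/dp_i = -(2 g_i (tot+eps) - (2 inter+eps)) / (tot+eps)^2
  dDdp <- -(sweep(2 * gm, 2, tot + eps, "*") -
              matrix(2 * inter + eps, HW, B, byrow = TRUE)) /
    matrix((tot + eps)^2, HW, B, byrow = TRUE)
  d_dice <- as.vector(dDdp) / B * prob * (1 - prob)
  switch(loss,
    dice          = list(loss = l_dice, dlogit = d_dice, dice = mean(dvals)),
    cross_entropy = list(loss = l_bce, dlogit = d_bce, dice = mean(dvals)),
    sum           = list(loss = l_bce + l_dice, dlogit = d_bce + d_dice,
                         dice = mean(dvals)))
}

# full backward pass -> list of gradients in parameter order
.net_backward <- function(model, cache, dlogit, B) {
  cfg <- model$config
  S <- cfg$input_size
  grads <- list(head = list(
    dW = crossprod(cache$A_last, dlogit),
    db = colSums(dlogit)))
  dA <- dlogit %*% t(model$head$W)
  gb <- vector("list", length(model$blocks))
  for (bl in rev(seq_along(model$blocks))) {
    blk <- model$blocks[[bl]]
    cc <- cache$blocks[[bl]]
    ind <- .im2col_index_batch(S, S, cfg$dilations[bl], B, model$idx_cache)
    dS <- dA * (cc$O > 0)
    g2 <- .conv_backward(dS, cc$cols2, ind, blk$W2, ncol(cc$A1))
    dZ1 <- g2$dX * (cc$A1 > 0)
    g1 <- .conv_backward(dZ1, cc$cols1, ind, blk$W1, cc$C_in)
    dA <- g1$dX + .skip_backward(dS, cc$C_in)
    gb[[bl]] <- list(dW1 = g1$dW, db1 = g1$db, dW2 = g2$dW, db2 = g2$db)
  }
  grads$blocks <- gb
  grads
}

# flatten / unflatten parameters for the optimizer and for checkpoints
.param_list <- function(model) {
  ps <- list()
  for (bl in seq_along(model$blocks)) {
    blk <- model$blocks[[bl]]
    ps[[sprintf("b%d.W1", bl)]] <- blk$W1; ps[[sprintf("b%d.b1", bl)]] <- blk$b1
    ps[[sprintf("b%d.W2", bl)]] <- blk$W2; ps[[sprintf("b%d.b2", bl)]] <- blk$b2
  }
  ps[["head.W"]] <- model$head$W; ps[["head.b"]] <- model$head$b
  ps
}

.grad_list <- function(grads) {
  gs <- list()
  for (bl in seq_along(grads$blocks)) {
    g <- grads$blocks[[bl]]
    gs[[sprintf("b%d.W1", bl)]] <- g$dW1; gs[[sprintf("b%d.b1", bl)]] <- g$db1
    gs[[sprintf("b%d.W2", bl)]] <- g$dW2; gs[[sprintf("b%d.b2", bl)]] <- g$db2
  }
  gs[["head.W"]] <- grads$head$dW; gs[["head.b"]] <- grads$head$db
  gs
}

.set_params <- function(model, ps) {
  for (bl in seq_along(model$blocks)) {
    model$blocks[[bl]]$W1 <- ps[[sprintf("b%d.W1", bl)]]
    model$blocks[[bl]]$b1 <- ps[[sprintf("b%d.b1", bl)]]
    model$blocks[[bl]]$W2 <- ps[[sprintf("b%d.W2", bl)]]
    model$blocks[[bl]]$b2 <- ps[[sprintf("b%d.b2", bl)]]
  }
  model$head$W <- ps[["head.W"]]
  model$head$b <- ps[["head.b"]]
  model
}

.adam_init <- function(ps) {
  list(m = lapply(ps, function(p) p * 0),
       v = lapply(ps, function(p) p * 0), t = 0L)
}

.adam_step <- function(ps, gs, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(ps)) {
    g <- gs[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    ps[[nm]] <- ps[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(ps = ps, state = state)
}
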