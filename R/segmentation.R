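# 2D lung segmentation on scout-like projections: a residual dilated
# convolutional network (built, trained and applied here) and a
# deterministic classical segmenter used as oracle/fallback.

#' Segmentation network configuration
#'
#' A 2D semantic-segmentation network of `n_conv_layers` 3x3 convolutions
#' in which every `residual_span` (= 2) consecutive layers form a residual
#' block, and different feature scales are reached through per-block
#' dilation factors rather than pooling. A final 1x1 scoring convolution
#' with a sigmoid maps features to a per-pixel lung probability.
#'
#' The defaults describe the desk-scale training protocol used by this
#' package's synthetic benchmark (64x64 inputs, 8 channels per block); wider
#' layouts (e.g. 32-64 channels at 256x256) are expressed through the same
#' configuration.
#'
#' @param n_conv_layers total number of 3x3 convolutional layers (even).
#' @param residual_span layers per residual block; the architecture is
#'   defined for a span of 2.
#' @param dilations integer dilation factor per block
#'   (length `n_conv_layers / residual_span`, all >= 1).
#' @param channels channel width per block (same length as `dilations`).
#' @param input_size square input size in pixels.
#' @param loss `"sum"` (Dice + cross-entropy), `"dice"` or
#'   `"cross_entropy"`.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param split named fractions `c(train=, val=, test=)` summing to 1.
#' @param seed integer seed controlling initialization and data order.
#' @return An object of class `seg_model_config`.
#' @export
seg_model_config <- function(n_conv_layers = 20, residual_span = 2,
                             dilations = c(1, 1, 2, 2, 4, 4, 8, 8, 4, 2),
                             channels = rep(8, 10),
                             input_size = 64,
                             loss = c("sum", "dice", "cross_entropy"),
                             lr = 1e-3, epochs = 10, batch_size = 8,
                             split = c(train = 0.7, val = 0.1, test = 0.2),
                             seed = 42) {
  loss <- match.arg(loss)
  if (n_conv_layers %% 2 != 0) stop("n_conv_layers must be even")
  if (residual_span != 2) stop("the architecture is defined for residual_span = 2")
  n_blocks <- n_conv_layers / residual_span
  if (length(dilations) != n_blocks)
    stop("dilations must have length n_conv_layers / residual_span")
  if (any(dilations < 1)) stop("dilation factors must be >= 1")
  if (length(channels) != n_blocks) stop("channels must have one width per block")
  if (any(channels < 1)) stop("channel widths must be positive")
  if (input_size < 32) stop("input_size must be >= 32")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (any(split[c("train", "val")] <= 0)) stop("train and val fractions must be positive")
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 residual_span = as.integer(residual_span),
                 dilations = as.integer(dilations),
                 channels = as.integer(channels),
                 input_size = as.integer(input_size), loss = loss,
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 seed = as.integer(seed)),
            class = "seg_model_config")
}

#' Build the residual dilated segmentation network
#'
#' Initializes all convolution weights (He initialization, seeded from the
#' configuration) for the architecture described in [seg_model_config()].
#'
#' @param config a [seg_model_config()].
#' @return An object of class `seg_model` with elements `config`, `blocks`
#'   (per-block convolution parameters), `head` (1x1 scoring convolution)
#'   and `n_params`.
#' @export
build_model <- function(config = seg_model_config()) {
  stopifnot(inherits(config, "seg_model_config"))
  n_blocks <- length(config$dilations)
  withr::with_seed(config$seed, {
    blocks <- vector("list", n_blocks)
    c_in <- 1L
    for (bl in seq_len(n_blocks)) {
      c_out <- config$channels[bl]
      he1 <- sqrt(2 / (9 * c_in)); he2 <- sqrt(2 / (9 * c_out))
      blocks[[bl]] <- list(
        W1 = matrix(rnorm(9 * c_in * c_out, 0, he1), 9 * c_in, c_out),
        b1 = numeric(c_out),
        W2 = matrix(rnorm(9 * c_out * c_out, 0, he2), 9 * c_out, c_out),
        b2 = numeric(c_out))
      c_in <- c_out
    }
    head <- list(W = matrix(rnorm(c_in, 0, sqrt(2 / c_in)), c_in, 1), b = 0)
  })
  n_params <- sum(vapply(blocks, function(b)
    length(b$W1) + length(b$b1) + length(b$W2) + length(b$b2), numeric(1))) +
    length(head$W) + 1L
  structure(list(config = config, blocks = blocks, head = head,
                 n_params = n_params, idx_cache = new.env(parent = emptyenv())),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> %d conv layers in %d residual blocks, %d parameters, input %dx%d\n",
              x$config$n_conv_layers, length(x$blocks), x$n_params,
              x$config$input_size, x$config$input_size))
  invisible(x)
}

# stack a list of (projection, mask) pairs into flat matrices
.stack_batch <- function(dataset, ids, S) {
  B <- length(ids)
  X <- matrix(0, B * S * S, 1)
  G <- numeric(B * S * S)
  for (i in seq_len(B)) {
    d <- dataset[[ids[i]]]
    X[((i - 1) * S * S + 1):(i * S * S), 1] <- as.vector(d$image$pixels)
    G[((i - 1) * S * S + 1):(i * S * S)] <- as.vector(d$mask$pixels) * 1
  }
  list(X = X, G = G)
}

.check_pair <- function(d, S) {
  if (!inherits(d$image, "projection2d") || !inherits(d$mask, "mask2d"))
    stop("dataset entries must be lists with a projection2d `image` and mask2d `mask`")
  if (is.null(d$image$normalization))
    stop("training images must be normalized (see normalize_resize)")
  if (!all(dim(d$image$pixels) == c(S, S)) || !all(dim(d$mask$pixels) == c(S, S)))
    stop("image/mask shape does not match the model input size")
}

.mean_val_dice <- function(model, dataset, ids, S, batch_size) {
  if (length(ids) == 0L) return(NA_real_)
  ds <- numeric(0)
  for (chunk in split(ids, ceiling(seq_along(ids) / batch_size))) {
    bt <- .stack_batch(dataset, chunk, S)
    pr <- .net_forward(model, bt$X, length(chunk))$prob
    pm <- matrix(pr >= 0.5, S * S, length(chunk))
    gm <- matrix(bt$G > 0.5, S * S, length(chunk))
    ds <- c(ds, vapply(seq_along(chunk), function(i)
      dice(matrix(pm[, i], S, S), matrix(gm[, i], S, S)), numeric(1)))
  }
  mean(ds)
}

#' Train (or fine-tune) the segmentation network
#'
#' Minimizes the configured loss with Adam over seeded minibatches. The
#' dataset is split deterministically into train/validation/test subsets;
#' the test subset is never touched and its indices are returned in the
#' report. Passing an already-trained model warm-starts the weights
#' (fine-tuning); `epochs = 0` returns the model unchanged along with its
#' initial validation Dice.
#'
#' @param model a [build_model()] network (fresh or pre-trained).
#' @param dataset list of `list(image = projection2d, mask = mask2d)` pairs,
#'   at least 20, normalized to the model input size.
#' @param config training configuration; defaults to the model's own.
#' @return A list with elements `model` (trained) and `report`
#'   (class `train_report`: split sizes, per-epoch training loss and
#'   validation Dice, `final_val_dice`, `test_indices`, `seed`).
#' @export
train <- function(model, dataset, config = model$config) {
  stopifnot(inherits(model, "seg_model"), inherits(config, "seg_model_config"))
  n <- length(dataset)
  if (n < 20L) stop("dataset must contain at least 20 image/mask pairs")
  S <- model$config$input_size
  for (d in dataset) .check_pair(d, S)

  withr::with_seed(config$seed, {
    perm <- sample.int(n)
    n_tr <- max(1L, round(config$split[["train"]] * n))
    n_va <- max(1L, round(config$split[["val"]] * n))
    n_tr <- min(n_tr, n - n_va)
    tr_ids <- perm[seq_len(n_tr)]
    va_ids <- perm[(n_tr + 1):(n_tr + n_va)]
    te_ids <- if (n_tr + n_va < n) perm[(n_tr + n_va + 1):n] else integer(0)

    epoch_loss <- numeric(0); epoch_val_dice <- numeric(0)
    if (config$epochs > 0L) {
      ps <- .param_list(model)
      state <- .adam_init(ps)
      for (ep in seq_len(config$epochs)) {
        ord <- sample(tr_ids)
        losses <- numeric(0)
        for (chunk in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
          bt <- .stack_batch(dataset, chunk, S)
          fwd <- .net_forward(model, bt$X, length(chunk), keep_cache = TRUE)
          ld <- .loss_and_dlogit(fwd$prob, bt$G, length(chunk), config$loss)
          grads <- .net_backward(model, fwd$cache, ld$dlogit, length(chunk))
          upd <- .adam_step(ps, .grad_list(grads), state, config$lr)
          ps <- upd$ps; state <- upd$state
          model <- .set_params(model, ps)
          losses <- c(losses, ld$loss)
        }
        epoch_loss <- c(epoch_loss, mean(losses))
        epoch_val_dice <- c(epoch_val_dice,
                            .mean_val_dice(model, dataset, va_ids, S, config$batch_size))
      }
    }
    final_val <- .mean_val_dice(model, dataset, va_ids, S, config$batch_size)
  })

  report <- structure(list(split = config$split,
                           n = c(train = length(tr_ids), val = length(va_ids),
                                 test = length(te_ids)),
                           epoch_loss = epoch_loss,
                           epoch_val_dice = epoch_val_dice,
                           final_val_dice = final_val,
                           test_indices = te_ids, seed = config$seed),
                      class = "train_report")
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> n = %d/%d/%d (train/val/test), %d epochs, final val Dice %.3f\n",
              x$n["train"], x$n["val"], x$n["test"],
              length(x$epoch_loss), x$final_val_dice))
  invisible(x)
}

#' Predict a 2D lung mask with the trained network
#'
#' @param model a trained [build_model()] network.
#' @param p a normalized [projection2d()] at the model input size.
#' @param threshold probability threshold for the binary mask.
#' @return A [mask2d()] sharing `p`'s row-to-z mapping.
#' @export
predict_mask <- function(model, p, threshold = 0.5) {
  stopifnot(inherits(model, "seg_model"), inherits(p, "projection2d"))
  S <- model$config$input_size
  if (is.null(p$normalization))
    stop("projection must be normalized before prediction (see normalize_resize)")
  if (!all(dim(p$pixels) == c(S, S)))
    stop("projection size does not match the model input size")
  prob <- .net_forward(model, matrix(as.vector(p$pixels), ncol = 1), 1L)$prob
  mask2d(matrix(prob >= threshold, S, S), p$row_to_z)
}

#' Per-pixel lung probability map
#'
#' @inheritParams predict_mask
#' @return Numeric matrix of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, p) {
  stopifnot(inherits(model, "seg_model"), inherits(p, "projection2d"))
  S <- model$config$input_size
  if (!all(dim(p$pixels) == c(S, S)))
    stop("projection size does not match the model input size")
  matrix(.net_forward(model, matrix(as.vector(p$pixels), ncol = 1), 1L)$prob, S, S)
}

#' Deterministic classical lung segmentation on a projection
#'
#' Training-free oracle/fallback segmenter. The body is everything above
#' the air floor (`body_threshold` of the normalized intensity range),
#' reduced to its largest connected component with holes filled. Within
#' the body, a per-column attenuation background is estimated as the
#' column maximum over body rows; lungs are found by hysteresis on the
#' relative attenuation deficit against that background: connected
#' regions exceeding `weak_threshold` are kept when they contain at least
#' one pixel exceeding `deficit_threshold`. The weak level recovers thin
#' structures (tapered apices, the costophrenic sliver) that attenuate
#' only faintly. Holes are filled and the two largest components kept.
#'
#' @param p a normalized [projection2d()].
#' @param deficit_threshold strong (seed) relative-deficit threshold.
#' @param weak_threshold weak (extension) relative-deficit threshold.
#' @param body_threshold normalized-intensity floor separating body from
#'   surrounding air.
#' @return A [mask2d()]; an image without a detectable body is an error.
#' @export
classical_segment <- function(p, deficit_threshold = 0.08,
                              weak_threshold = 0.025,
                              body_threshold = 0.05) {
  stopifnot(inherits(p, "projection2d"))
  if (is.null(p$normalization))
    stop("projection must be normalized before segmentation (see normalize_resize)")
  px <- p$pixels
  if (diff(range(px)) == 0) stop("no body found (constant image)")
  body <- px > body_threshold
  if (!any(body)) stop("no body found")
  lbl <- EBImage::bwlabel(body * 1)
  sizes <- tabulate(lbl[lbl > 0])
  body <- matrix(lbl == which.max(sizes), nrow(px), ncol(px))
  body <- EBImage::fillHull(body * 1) > 0

  bg <- apply(ifelse(body, px, NA), 2, function(col)
    if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE))
  deficit <- 1 - sweep(px, 2, bg, "/")
  deficit[is.na(deficit)] <- 0
  strong <- body & deficit > deficit_threshold
  weak <- body & deficit > min(weak_threshold, deficit_threshold)
  lw <- EBImage::bwlabel(weak * 1)
  seeded <- setdiff(unique(lw[strong]), 0)
  lung <- matrix(lw %in% seeded, nrow(px), ncol(px))
  if (any(lung)) {
    lung <- EBImage::fillHull(lung * 1) > 0
    ll <- EBImage::bwlabel(lung * 1)
    ls <- tabulate(ll[ll > 0])
    keep <- order(ls, decreasing = TRUE)[seq_len(min(2L, length(ls)))]
    lung <- matrix(ll %in% keep, nrow(px), ncol(px))
  } else {
    warning("no lung-like region found; returning an empty mask")
  }
  mask2d(lung, p$row_to_z)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A ∩ B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [mask2d()] objects or logical matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  pa <- if (inherits(a, "mask2d")) a$pixels else a
  pb <- if (inherits(b, "mask2d")) b$pixels else b
  if (!all(dim(pa) == dim(pb))) stop("mask shapes differ")
  sa <- sum(pa); sb <- sum(pb)
  if (sa + sb == 0) return(1)
  2 * sum(pa & pb) / (sa + sb)
}

#' Save / load a segmentation model checkpoint
#'
#' Single-file checkpoint with the configuration embedded.
#'
#' @param model a [build_model()] network.
#' @param path file path (`.rds`).
#' @return `save_seg_model()` returns `path` invisibly; `load_seg_model()`
#'   returns the model.
#' @export
save_seg_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  obj <- model
  obj$idx_cache <- NULL
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_seg_model
#' @export
load_seg_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "seg_model")) stop("not a seg_model checkpoint")
  obj$idx_cache <- new.env(parent = emptyenv())
  obj
}
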