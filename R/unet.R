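#' U-Net configuration
#'
#' Describes an encoder--decoder segmentation network. Each encoder level
#' applies two 3x3 same-padded convolutions (ReLU) followed by 2x2 max
#' pooling; the bottleneck applies two further convolutions; each decoder
#' level applies a 2x2 transposed convolution, concatenation with the
#' mirror-image encoder feature map (a skip connection at every level), and
#' two convolutions; a final 1x1 convolution plus sigmoid yields the
#' probability map. The vanilla variant defaults to depth 4, the multi-layer
#' gray-matter variant to depth 3, with filter counts doubling per level.
#'
#' @param depth Number of encoder levels.
#' @param filters Integer vector of per-level filter counts
#'   (length \code{depth}); defaults to \code{base_filters * 2^(0:(depth-1))}.
#' @param bottleneck_filters Filter count of the bottleneck block
#'   (default: twice the deepest level).
#' @param input_size Side length of the (square) input; must be divisible by
#'   \code{2^depth}.
#' @param base_filters Base filter count used when \code{filters} is NULL.
#' @param variant "multilayer" (depth 3) or "vanilla" (depth 4); sets the
#'   default depth only.
#' @return An object of class \code{unet_config}.
#' @export
unet_config <- function(depth = NULL, filters = NULL, bottleneck_filters = NULL,
                        input_size = 224, base_filters = 32,
                        variant = c("multilayer", "vanilla")) {
  variant <- match.arg(variant)
  if (is.null(depth)) depth <- if (variant == "vanilla") 4L else 3L
  depth <- as.integer(depth)
  if (is.null(filters)) filters <- base_filters * 2^(seq_len(depth) - 1L)
  filters <- as.integer(filters)
  if (is.null(bottleneck_filters)) bottleneck_filters <- 2L * filters[depth]
  if (length(filters) != depth)
    stop("`filters` must have one entry per encoder level (depth = ",
         depth, ")", call. = FALSE)
  if (any(filters < 1) || bottleneck_filters < 1)
    stop("filter counts must be >= 1", call. = FALSE)
  if (input_size %% 2^depth != 0)
    stop("input_size ", input_size, " is not divisible by 2^depth = ",
         2^depth, call. = FALSE)
  structure(list(depth = depth, filters = filters,
                 bottleneck_filters = as.integer(bottleneck_filters),
                 input_size = as.integer(input_size), variant = variant),
            class = "unet_config")
}

#' Build a U-Net segmentation model
#'
#' Instantiates the weights of the network described by a
#' \code{\link{unet_config}}. Convolutions are 3x3, zero-padded "same", with
#' ReLU activations; up-sampling uses 2x2 stride-2 transposed convolutions;
#' the head is a 1x1 convolution with a sigmoid. Weights are He-initialised
#' from the session RNG (or from \code{seed} when given).
#'
#' @param config A \code{unet_config}.
#' @param seed Optional integer seed for weight initialisation.
#' @return An object of class \code{unet_model}.
#' @export
build_unet <- function(config, seed = NULL) {
  stopifnot(inherits(config, "unet_config"))
  make <- function() {
    d <- config$depth; f <- config$filters
    enc <- vector("list", d)
    cin <- 1L
    for (i in seq_len(d)) {
      enc[[i]] <- list(conv1 = nn_init_conv(3L, cin, f[i]),
                       conv2 = nn_init_conv(3L, f[i], f[i]))
      cin <- f[i]
    }
    fb <- config$bottleneck_filters
    bott <- list(conv1 = nn_init_conv(3L, f[d], fb),
                 conv2 = nn_init_conv(3L, fb, fb))
    dec <- vector("list", d)
    prev <- fb
    for (i in rev(seq_len(d))) {
      dec[[i]] <- list(tconv = nn_init_tconv(prev, f[i]),
                       conv1 = nn_init_conv(3L, 2L * f[i], f[i]),
                       conv2 = nn_init_conv(3L, f[i], f[i]))
      prev <- f[i]
    }
    out <- list(conv = nn_init_conv(1L, f[1], 1L))
    structure(list(config = config,
                   params = list(enc = enc, bott = bott, dec = dec, out = out)),
              class = "unet_model")
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Number of trainable parameters of a U-Net
#'
#' @param model A \code{unet_model}.
#' @return Integer parameter count (weights plus biases).
#' @export
n_params <- function(model) {
  cnt <- function(p) {
    if (is.list(p) && !is.null(p$type)) length(p$W) + length(p$b)
    else if (is.list(p)) sum(vapply(p, cnt, numeric(1)))
    else 0
  }
  as.integer(cnt(model$params))
}

conv_fw_ <- function(x, H, W, lay) nn_conv_fw(x, H, W, lay$cin, lay$W, lay$b, lay$k)

# flatten nested params into the fixed W/b order expected by unet_fw_bw():
# enc (conv1, conv2 per level), bottleneck, dec (tconv, conv1, conv2 per
# level, shallowest first), output conv
unet_flatten <- function(params) {
  out <- list()
  push <- function(l) out[c(length(out) + 1L, length(out) + 2L)] <<-
    list(l$W, matrix(l$b, 1L))
  for (e in params$enc) { push(e$conv1); push(e$conv2) }
  push(params$bott$conv1); push(params$bott$conv2)
  for (dl in params$dec) { push(dl$tconv); push(dl$conv1); push(dl$conv2) }
  push(params$out$conv)
  out
}

# rebuild a minimal nested gradient structure (W/b leaves only) from the
# flat gradient list returned by unet_fw_bw()
unet_grads_nested <- function(params, flat) {
  t <- 0L
  pull <- function() {
    g <- list(W = flat[[t + 1L]], b = as.numeric(flat[[t + 2L]]))
    t <<- t + 2L
    g
  }
  g <- list(enc = vector("list", length(params$enc)),
            dec = vector("list", length(params$dec)))
  for (i in seq_along(params$enc))
    g$enc[[i]] <- list(conv1 = pull(), conv2 = pull())
  g$bott <- list(conv1 = pull(), conv2 = pull())
  for (i in seq_along(params$dec))
    g$dec[[i]] <- list(tconv = pull(), conv1 = pull(), conv2 = pull())
  g$out <- list(conv = pull())
  g
}

unet_unflatten <- function(params, flat) {
  t <- 0L
  pull <- function(l) {
    l$W <- matrix(flat[[t + 1L]], nrow(l$W), ncol(l$W))
    l$b <- as.numeric(flat[[t + 2L]])
    t <<- t + 2L
    l
  }
  for (i in seq_along(params$enc)) {
    params$enc[[i]]$conv1 <- pull(params$enc[[i]]$conv1)
    params$enc[[i]]$conv2 <- pull(params$enc[[i]]$conv2)
  }
  params$bott$conv1 <- pull(params$bott$conv1)
  params$bott$conv2 <- pull(params$bott$conv2)
  for (i in seq_along(params$dec)) {
    params$dec[[i]]$tconv <- pull(params$dec[[i]]$tconv)
    params$dec[[i]]$conv1 <- pull(params$dec[[i]]$conv1)
    params$dec[[i]]$conv2 <- pull(params$dec[[i]]$conv2)
  }
  params$out$conv <- pull(params$out$conv)
  params
}

# fused single-precision forward(/backward) pass
unet_step <- function(model, image, y = NULL, loss = "balanced_bce",
                      beta = 0.5, backward = FALSE) {
  cfg <- model$config
  if (nrow(image) != cfg$input_size || ncol(image) != cfg$input_size)
    stop("image must be ", cfg$input_size, "x", cfg$input_size, call. = FALSE)
  unet_fw_bw(unet_flatten(model$params), cfg$filters, cfg$bottleneck_filters,
             cfg$input_size, image, y, loss, beta, backward)
}

# reference double-precision forward pass (layer by layer); returns logits
# (H x W matrix) and the cache for backward
unet_forward <- function(model, image) {
  cfg <- model$config
  H <- nrow(image)
  if (H != cfg$input_size || ncol(image) != cfg$input_size)
    stop("image must be ", cfg$input_size, "x", cfg$input_size, call. = FALSE)
  p <- model$params
  d <- cfg$depth
  cache <- list(enc = vector("list", d), dec = vector("list", d))
  cur <- matrix(as.numeric(image), H * H, 1L)
  h <- H
  for (i in seq_len(d)) {
    e <- list(x = cur, h = h)
    e$z1 <- conv_fw_(cur, h, h, p$enc[[i]]$conv1); e$a1 <- nn_relu(e$z1)
    e$z2 <- conv_fw_(e$a1, h, h, p$enc[[i]]$conv2); e$a2 <- nn_relu(e$z2)
    pl <- nn_pool_fw(e$a2, h, h, ncol(e$a2))
    e$amax <- pl$amax
    cache$enc[[i]] <- e
    cur <- pl$y
    h <- h %/% 2L
  }
  cache$bott <- list(x = cur, h = h)
  cache$bott$z1 <- conv_fw_(cur, h, h, p$bott$conv1)
  cache$bott$a1 <- nn_relu(cache$bott$z1)
  cache$bott$z2 <- conv_fw_(cache$bott$a1, h, h, p$bott$conv2)
  cache$bott$a2 <- nn_relu(cache$bott$z2)
  cur <- cache$bott$a2
  for (i in rev(seq_len(d))) {
    dcl <- list(x = cur, h = h)
    lay <- p$dec[[i]]
    up <- nn_tconv_fw(cur, h, h, lay$tconv$cin, lay$tconv$W, lay$tconv$b,
                      lay$tconv$cout)
    h <- 2L * h
    skip <- cache$enc[[i]]$a2
    dcl$up <- up
    dcl$cat <- cbind(up, skip)
    dcl$z1 <- conv_fw_(dcl$cat, h, h, lay$conv1); dcl$a1 <- nn_relu(dcl$z1)
    dcl$z2 <- conv_fw_(dcl$a1, h, h, lay$conv2); dcl$a2 <- nn_relu(dcl$z2)
    cache$dec[[i]] <- dcl
    cur <- dcl$a2
  }
  cache$pre_out <- cur
  logits <- conv_fw_(cur, H, H, p$out$conv)
  list(logits = matrix(logits, H, H), cache = cache)
}

# backward pass: gradient of the loss w.r.t. all parameters (and the input)
unet_backward <- function(model, cache, dlogits) {
  cfg <- model$config; p <- model$params; d <- cfg$depth
  H <- cfg$input_size
  g <- list(enc = vector("list", d), dec = vector("list", d))
  gl <- matrix(as.numeric(dlogits), H * H, 1L)
  bw <- nn_conv_bw(cache$pre_out, gl, H, H, p$out$conv$cin, p$out$conv$W, 1L)
  g$out <- list(conv = list(W = bw$gW, b = as.numeric(bw$gb)))
  gcur <- bw$gx
  h <- H
  for (i in seq_len(d)) {
    dcl <- cache$dec[[i]]; lay <- p$dec[[i]]
    gz2 <- nn_relu_bw(dcl$z2, gcur)
    b2 <- nn_conv_bw(dcl$a1, gz2, h, h, lay$conv2$cin, lay$conv2$W, 3L)
    gz1 <- nn_relu_bw(dcl$z1, b2$gx)
    b1 <- nn_conv_bw(dcl$cat, gz1, h, h, lay$conv1$cin, lay$conv1$W, 3L)
    f <- cfg$filters[i]
    gup <- b1$gx[, seq_len(f), drop = FALSE]
    gskip <- b1$gx[, f + seq_len(f), drop = FALSE]
    bt <- nn_tconv_bw(dcl$x, gup, dcl$h, dcl$h, lay$tconv$cin, lay$tconv$W,
                      lay$tconv$cout)
    g$dec[[i]] <- list(tconv = list(W = bt$gW, b = as.numeric(bt$gb)),
                       conv1 = list(W = b1$gW, b = as.numeric(b1$gb)),
                       conv2 = list(W = b2$gW, b = as.numeric(b2$gb)))
    cache$enc[[i]]$gskip <- gskip   # accumulated when the encoder is unwound
    gcur <- bt$gx
    h <- dcl$h
  }
  bo <- cache$bott
  gz2 <- nn_relu_bw(bo$z2, gcur)
  b2 <- nn_conv_bw(bo$a1, gz2, h, h, p$bott$conv2$cin, p$bott$conv2$W, 3L)
  gz1 <- nn_relu_bw(bo$z1, b2$gx)
  b1 <- nn_conv_bw(bo$x, gz1, h, h, p$bott$conv1$cin, p$bott$conv1$W, 3L)
  g$bott <- list(conv1 = list(W = b1$gW, b = as.numeric(b1$gb)),
                 conv2 = list(W = b2$gW, b = as.numeric(b2$gb)))
  gcur <- b1$gx
  for (i in rev(seq_len(d))) {
    e <- cache$enc[[i]]; lay <- p$enc[[i]]
    h <- e$h
    ga2 <- nn_pool_bw(gcur, e$amax, h, h, ncol(e$a2)) + e$gskip
    gz2 <- nn_relu_bw(e$z2, ga2)
    b2 <- nn_conv_bw(e$a1, gz2, h, h, lay$conv2$cin, lay$conv2$W, 3L)
    gz1 <- nn_relu_bw(e$z1, b2$gx)
    b1 <- nn_conv_bw(e$x, gz1, h, h, lay$conv1$cin, lay$conv1$W, 3L)
    g$enc[[i]] <- list(conv1 = list(W = b1$gW, b = as.numeric(b1$gb)),
                       conv2 = list(W = b2$gW, b = as.numeric(b2$gb)))
    gcur <- b1$gx
  }
  list(grads = g, ginput = matrix(gcur, H, H))
}

#' Class-balanced binary cross-entropy loss
#'
#' Mean over pixels of \eqn{-\beta y \log p - (1-\beta)(1-y)\log(1-p)}, where
#' the weight \eqn{\beta \in (0,1)} up-weights the foreground (tissue) term to
#' counter the background-dominated pixel balance of brain masks. Predictions
#' are clipped to \code{[1e-7, 1 - 1e-7]} before the logs. The endpoints
#' beta = 0 and beta = 1 annihilate one term entirely and are accepted for
#' the loss itself; training configurations require a strictly interior
#' weight.
#'
#' @param y_true Binary ground-truth mask (matrix of 0/1).
#' @param y_pred Predicted probability map, same shape.
#' @param beta Foreground weight in [0, 1].
#' @return Non-negative scalar loss.
#' @export
balanced_cross_entropy <- function(y_true, y_pred, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0 || beta > 1)
    stop("`beta` must be a single number in [0, 1]", call. = FALSE)
  if (!all(dim(y_true) == dim(y_pred)))
    stop("mask and prediction shapes differ", call. = FALSE)
  eps <- 1e-7
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  mean(-beta * y_true * log(p) - (1 - beta) * (1 - y_true) * log(1 - p))
}

#' Soft Dice loss
#'
#' \eqn{1 - (2\sum p y + s) / (\sum p + \sum y + s)} with smoothing constant
#' \eqn{s} (default 1), defined on probability maps; two empty masks give 0.
#'
#' @inheritParams balanced_cross_entropy
#' @param smooth Smoothing constant added to numerator and denominator.
#' @return Scalar loss in [0, 1].
#' @export
dice_loss <- function(y_true, y_pred, smooth = 1) {
  if (!all(dim(y_true) == dim(y_pred)))
    stop("mask and prediction shapes differ", call. = FALSE)
  1 - (2 * sum(y_pred * y_true) + smooth) /
    (sum(y_pred) + sum(y_true) + smooth)
}

# gradient of the chosen loss w.r.t. the logits (probability p = sigmoid(z))
seg_loss_grad <- function(y, p, loss, beta, smooth = 1) {
  n <- length(y)
  if (loss == "balanced_bce") {
    (-beta * y * (1 - p) + (1 - beta) * (1 - y) * p) / n
  } else {
    den <- sum(p) + sum(y) + smooth
    num <- 2 * sum(p * y) + smooth
    dp <- -(2 * y * den - num) / den^2
    dp * p * (1 - p)
  }
}

#' Segmentation training configuration
#'
#' Defaults mirror the reference training recipe: Adam, learning rate 1e-4,
#' batch size 8, 100 epochs, balanced cross-entropy with automatic class
#' weight. \code{beta = "auto"} sets the foreground weight to the background
#' pixel fraction of the training masks, so tissue errors are up-weighted in
#' proportion to the imbalance.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param loss "balanced_bce" or "dice".
#' @param beta Numeric in (0,1), or "auto".
#' @param seed Integer seed controlling initialisation order and shuffling.
#' @return An object of class \code{seg_train_config}.
#' @export
seg_train_config <- function(learning_rate = 1e-4, batch_size = 8,
                             epochs = 100, loss = c("balanced_bce", "dice"),
                             beta = "auto", seed = 42) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (is.numeric(beta) && (beta <= 0 || beta >= 1))
    stop("numeric `beta` must lie in (0, 1)", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss, beta = beta,
                 seed = as.integer(seed)),
            class = "seg_train_config")
}

#' Train a U-Net segmenter
#'
#' Mini-batch Adam training under the configured loss; after every epoch the
#' validation Dice (threshold 0.5) is evaluated and the weights achieving the
#' best validation Dice are retained. Fully deterministic for a fixed
#' \code{config$seed}.
#'
#' @param model A \code{unet_model} (its weights are the starting point).
#' @param train_images,train_masks Lists of matrices (images in [0,1], masks
#'   strictly binary).
#' @param val_images,val_masks Validation lists (may be the training lists for
#'   overfitting checks).
#' @param config A \code{\link{seg_train_config}}.
#' @return A \code{trained_segmenter}: the best model, per-epoch history
#'   (loss, val_dice), and the resolved beta.
#' @export
train_segmenter <- function(model, train_images, train_masks,
                            val_images, val_masks, config = seg_train_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "seg_train_config"))
  n <- length(train_images)
  if (n == 0) stop("empty training data", call. = FALSE)
  if (length(train_masks) != n) stop("images/masks length mismatch", call. = FALSE)
  for (m in train_masks)
    if (!all(m %in% c(0, 1))) stop("masks must be strictly binary", call. = FALSE)
  beta <- config$beta
  if (identical(beta, "auto"))
    beta <- mean(vapply(train_masks, function(m) mean(m == 0), numeric(1)))
  set.seed(config$seed)
  opt <- adam_init(model$params)
  hist <- data.frame(epoch = integer(), loss = numeric(), val_dice = numeric())
  best <- list(dice = -Inf, params = model$params)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      gacc <- NULL
      for (i in idx) {
        st <- unet_step(model, train_images[[i]], y = train_masks[[i]],
                        loss = config$loss, beta = beta, backward = TRUE)
        ep_loss <- ep_loss + st$loss
        gacc <- grad_add(gacc, unet_grads_nested(model$params, st$grads),
                         w = 1 / length(idx))
      }
      st <- adam_step(model$params, gacc, opt, config$learning_rate)
      model$params <- st$params
      opt <- st$state
    }
    vd <- mean(vapply(seq_along(val_images), function(i) {
      pm <- predict_mask(model, val_images[[i]])
      dice_coefficient(pm, val_masks[[i]])
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n, val_dice = vd))
    if (vd > best$dice) best <- list(dice = vd, params = model$params)
  }
  model$params <- best$params
  structure(list(model = model, history = hist, beta = beta,
                 best_val_dice = best$dice, config = config),
            class = "trained_segmenter")
}

#' Predict a binary mask from a trained or raw U-Net
#'
#' @param model A \code{unet_model} or \code{trained_segmenter}.
#' @param image Input slice (matrix matching the model's input size).
#' @param threshold Probability threshold; a pixel is foreground iff
#'   \eqn{p \ge} threshold.
#' @param probabilities If TRUE return the probability map instead.
#' @return Binary matrix (or probability matrix).
#' @export
predict_mask <- function(model, image, threshold = 0.5, probabilities = FALSE) {
  if (inherits(model, "trained_segmenter")) model <- model$model
  p <- nn_sigmoid(unet_step(model, image)$logits)
  if (probabilities) p else (p >= threshold) * 1
}
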