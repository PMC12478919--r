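#' Compact convolutional backbone
#'
#' The feature extractor behind classification is pluggable: any object
#' honouring the \code{\link{extract_features}} contract (image in, C x H' x
#' W' activations out) can stand in. The package ships this compact
#' random-initialised CNN -- stacked 3x3 conv / ReLU / 2x2 max-pool stages --
#' whose channel count and depth are configurable; a large pretrained
#' backbone (e.g. an EfficientNet-B0 final stage with 1280 channels and
#' overall stride 32) can be substituted through the same contract when its
#' activations are available.
#'
#' @param out_channels Channels of the final feature map.
#' @param input_size Expected input side in pixels.
#' @param base_channels Channels of the first stage; doubled per stage.
#' @param n_stages Number of conv/pool stages (overall stride 2^n_stages).
#' @param seed Integer seed for the (fixed) random weights.
#' @return A \code{conv_backbone} object.
#' @export
conv_backbone <- function(out_channels = 32, input_size = 64,
                          base_channels = 8, n_stages = 3, seed = 1) {
  if (input_size %% 2^n_stages != 0)
    stop("input_size must be divisible by 2^n_stages", call. = FALSE)
  chans <- c(base_channels * 2^(seq_len(n_stages) - 1L))
  chans[n_stages] <- out_channels
  with_seed(seed, {
    cin <- 1L
    stages <- lapply(chans, function(co) {
      l <- nn_init_conv(3L, cin, as.integer(co))
      cin <<- as.integer(co)
      l
    })
    structure(list(stages = stages, channels = as.integer(out_channels),
                   input_size = as.integer(input_size),
                   stride = 2L^n_stages),
              class = "conv_backbone")
  })
}

backbone_forward <- function(backbone, image) {
  S <- backbone$input_size
  if (!all(dim(image) == c(S, S)))
    stop("image must be ", S, "x", S, " for this backbone", call. = FALSE)
  cur <- matrix(as.numeric(image), S * S, 1L)
  h <- S
  cache <- list()
  for (t in seq_along(backbone$stages)) {
    lay <- backbone$stages[[t]]
    st <- list(x = cur, h = h)
    st$z <- conv_fw_(cur, h, h, lay)
    st$a <- nn_relu(st$z)
    pl <- nn_pool_fw(st$a, h, h, ncol(st$a))
    st$amax <- pl$amax
    cache[[t]] <- st
    cur <- pl$y
    h <- h %/% 2L
  }
  list(fmap = cur, h = h, cache = cache)
}

backbone_backward <- function(backbone, cache, gfmap) {
  gcur <- gfmap
  for (t in rev(seq_along(backbone$stages))) {
    st <- cache[[t]]
    lay <- backbone$stages[[t]]
    ga <- nn_pool_bw(gcur, st$amax, st$h, st$h, ncol(st$a))
    gz <- nn_relu_bw(st$z, ga)
    gcur <- nn_conv_bw(st$x, gz, st$h, st$h, lay$cin, lay$W, 3L)$gx
  }
  matrix(gcur, backbone$input_size, backbone$input_size)
}

#' Extract backbone feature maps
#'
#' Runs the backbone's convolutional stages over a slice and returns the
#' final-stage activations as an H' x W' x C array (spatial size
#' input_size / stride).
#'
#' @param backbone A \code{\link{conv_backbone}} (or compatible object).
#' @param image Matrix sized to the backbone's expected input.
#' @return 3D array of activations.
#' @export
extract_features <- function(backbone, image) {
  fw <- backbone_forward(backbone, image)
  array(fw$fmap, dim = c(fw$h, fw$h, backbone$channels))
}

#' Multi-scale head configuration
#'
#' Three parallel convolutional branches with kernel sizes 3 / 5 / 7 read the
#' backbone feature map at increasing receptive fields; each branch applies a
#' same-padded convolution, LeakyReLU, 2x2 max pooling, adaptive average
#' pooling to 1x1 and (in training) dropout. The branch outputs are
#' concatenated in fixed order into one feature vector of length
#' \code{3 * branch_channels}. A single-branch variant (kernel 3 only) is
#' allowed for single-scale ablations.
#'
#' @param kernel_sizes Odd kernel sizes, length 3 (default c(3, 5, 7)) or 1.
#' @param branch_channels Output channels per branch (default 128).
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.01).
#' @param dropout_rate Dropout probability during head training (default 0.3).
#' @return A \code{multi_scale_config}.
#' @export
multi_scale_config <- function(kernel_sizes = c(3, 5, 7),
                               branch_channels = 128, leaky_slope = 0.01,
                               dropout_rate = 0.3) {
  if (!length(kernel_sizes) %in% c(1L, 3L))
    stop("kernel_sizes must have length 3 (multi-scale) or 1 (single-scale)",
         call. = FALSE)
  if (any(kernel_sizes %% 2 == 0)) stop("kernel sizes must be odd", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 branch_channels = as.integer(branch_channels),
                 leaky_slope = leaky_slope, dropout_rate = dropout_rate),
            class = "multi_scale_config")
}

#' Build a multi-scale classification head
#'
#' Branch convolutions plus a linear softmax layer over the three diagnostic
#' classes appended to the concatenated feature vector.
#'
#' @param in_channels Channel count of the incoming feature map.
#' @param config A \code{\link{multi_scale_config}}.
#' @param seed Optional seed for weight initialisation.
#' @return A \code{multi_scale_head}.
#' @export
multi_scale_head <- function(in_channels, config = multi_scale_config(),
                             seed = NULL) {
  make <- function() {
    branches <- lapply(config$kernel_sizes, function(k)
      nn_init_conv(as.integer(k), as.integer(in_channels),
                   config$branch_channels))
    dfeat <- length(config$kernel_sizes) * config$branch_channels
    fc <- list(W = matrix(rnorm(dfeat * 3, sd = sqrt(1 / dfeat)), dfeat, 3),
               b = numeric(3))
    structure(list(config = config, in_channels = as.integer(in_channels),
                   params = list(branches = branches, fc = fc)),
              class = "multi_scale_head")
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

head_forward <- function(head, fmap, training = FALSE) {
  cfg <- head$config
  dm <- dim(fmap)
  if (length(dm) != 3 || dm[3] != head$in_channels)
    stop("feature-map channels (", if (length(dm) == 3) dm[3] else NA,
         ") do not match the head (", head$in_channels, ")", call. = FALSE)
  H <- dm[1]; W <- dm[2]
  x <- matrix(fmap, H * W, dm[3])
  bc <- cfg$branch_channels
  cache <- list(x = x, H = H, W = W, branches = list())
  feat <- numeric(0)
  for (t in seq_along(cfg$kernel_sizes)) {
    lay <- head$params$branches[[t]]
    br <- list()
    br$z <- nn_conv_fw(x, H, W, lay$cin, lay$W, lay$b, lay$k)
    br$a <- nn_leaky(br$z, cfg$leaky_slope)
    if (H %% 2 == 0 && W %% 2 == 0 && H >= 2) {
      pl <- nn_pool_fw(br$a, H, W, bc)
      br$pooled <- pl$y; br$amax <- pl$amax; br$pool_used <- TRUE
    } else {
      br$pooled <- br$a; br$pool_used <- FALSE
    }
    v <- colMeans(br$pooled)                 # adaptive average pool to 1x1
    if (training && cfg$dropout_rate > 0) {
      br$mask <- (runif(bc) >= cfg$dropout_rate) / (1 - cfg$dropout_rate)
      v <- v * br$mask
    }
    br$v <- v
    cache$branches[[t]] <- br
    feat <- c(feat, v)
  }
  logits <- as.numeric(crossprod(head$params$fc$W, feat)) + head$params$fc$b
  cache$feat <- feat
  list(feat = feat, logits = logits, probs = nn_softmax(logits), cache = cache)
}

head_backward <- function(head, cache, dlogits) {
  cfg <- head$config
  bc <- cfg$branch_channels
  H <- cache$H; W <- cache$W
  gfc <- list(W = cache$feat %o% dlogits, b = dlogits)
  gfeat <- as.numeric(head$params$fc$W %*% dlogits)
  gx <- NULL
  gbr <- vector("list", length(cfg$kernel_sizes))
  for (t in seq_along(cfg$kernel_sizes)) {
    lay <- head$params$branches[[t]]
    br <- cache$branches[[t]]
    gv <- gfeat[(t - 1) * bc + seq_len(bc)]
    if (!is.null(br$mask)) gv <- gv * br$mask
    np <- nrow(br$pooled)
    gpooled <- matrix(rep(gv / np, each = np), np, bc)
    ga <- if (br$pool_used) nn_pool_bw(gpooled, br$amax, H, W, bc) else gpooled
    gz <- nn_leaky_bw(br$z, ga, cfg$leaky_slope)
    bw <- nn_conv_bw(cache$x, gz, H, W, lay$cin, lay$W, lay$k)
    gbr[[t]] <- list(W = bw$gW, b = as.numeric(bw$gb))
    gx <- if (is.null(gx)) bw$gx else gx + bw$gx
  }
  list(grads = list(branches = gbr, fc = gfc), gfmap = gx)
}

#' Multi-scale feature vector of a feature map
#'
#' Forward pass of the multi-scale head up to the concatenated, flattened
#' feature vector (branch order fixed: F1 || F2 || F3). Dropout is applied
#' only when \code{training = TRUE} (drawing from the session RNG).
#'
#' @param head A \code{\link{multi_scale_head}}.
#' @param fmap H' x W' x C feature-map array.
#' @param training Logical; activates dropout.
#' @return Numeric vector of length \code{n_branches * branch_channels}.
#' @export
multi_scale_forward <- function(head, fmap, training = FALSE) {
  head_forward(head, fmap, training = training)$feat
}

#' Head training configuration
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @return A \code{clf_train_config}.
#' @export
clf_train_config <- function(learning_rate = 1e-4, batch_size = 32,
                             epochs = 10, seed = 42) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "clf_train_config")
}

#' Train the classification head by categorical cross-entropy
#'
#' The backbone stays frozen; its feature maps are computed once and the
#' multi-scale head plus linear softmax layer are optimised with Adam under
#' \eqn{L = -\sum_i y_i \log \hat y_i}. Deterministic for a fixed seed.
#'
#' @param backbone A \code{\link{conv_backbone}}.
#' @param head A \code{\link{multi_scale_head}}.
#' @param images List of input slices.
#' @param labels Class labels over \{AD, CN, MCI\}.
#' @param config A \code{\link{clf_train_config}}.
#' @return A \code{trained_head}: list(head, history, classes).
#' @export
train_head <- function(backbone, head, images, labels,
                       config = clf_train_config()) {
  n <- length(images)
  if (n == 0) stop("empty training data", call. = FALSE)
  cls <- stage_classes()
  labels <- as.character(labels)
  if (!all(labels %in% cls))
    stop("labels must lie in {AD, CN, MCI}", call. = FALSE)
  fmaps <- lapply(images, function(im) extract_features(backbone, im))
  yi <- match(labels, cls)
  set.seed(config$seed)
  opt <- adam_init(head$params)
  hist <- data.frame(epoch = integer(), loss = numeric())
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      gacc <- NULL
      for (i in idx) {
        fw <- head_forward(head, fmaps[[i]], training = TRUE)
        onehot <- numeric(3); onehot[yi[i]] <- 1
        ep_loss <- ep_loss - log(max(fw$probs[yi[i]], 1e-12))
        bwd <- head_backward(head, fw$cache, fw$probs - onehot)
        gacc <- grad_add(gacc, bwd$grads, w = 1 / length(idx))
      }
      st <- adam_step(head$params, gacc, opt, config$learning_rate)
      head$params <- st$params
      opt <- st$state
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n))
  }
  structure(list(head = head, history = hist, classes = cls),
            class = "trained_head")
}

#' Feature matrix for a set of images
#'
#' Backbone + multi-scale head forward (no dropout) for each image; rows are
#' the flattened feature vectors fed to the SVM.
#'
#' @param backbone A \code{conv_backbone}.
#' @param head A \code{multi_scale_head} or \code{trained_head}.
#' @param images List of input slices.
#' @return n x (n_branches * branch_channels) matrix.
#' @export
head_features <- function(backbone, head, images) {
  if (inherits(head, "trained_head")) head <- head$head
  t(vapply(images,
           function(im) multi_scale_forward(head, extract_features(backbone, im)),
           numeric(length(head$config$kernel_sizes) *
                     head$config$branch_channels)))
}

#' Fit a feature standardiser on training features
#'
#' Per-dimension mean and standard deviation; zero-variance dimensions get
#' scale 1 so constant columns are centred but not divided.
#'
#' @param train_features Numeric matrix (rows = samples).
#' @return A \code{feature_scaler} with fields mean and scale.
#' @export
fit_scaler <- function(train_features) {
  m <- colMeans(train_features)
  s <- apply(train_features, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  structure(list(mean = m, scale = s), class = "feature_scaler")
}

#' Apply a fitted standardiser
#'
#' @param scaler A \code{\link{fit_scaler}} result.
#' @param features Matrix (or vector) with matching dimensionality.
#' @return Standardised matrix.
#' @export
apply_scaler <- function(scaler, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  sweep(sweep(features, 2, scaler$mean), 2, scaler$scale, "/")
}

#' SVM hyper-parameter grid
#'
#' Grid cells are enumerated in a fixed, documented order used for tie
#' breaking: RBF before linear, larger C first, gamma "scale" before "auto".
#'
#' @param kernels Kernels to try (subset of "rbf", "linear").
#' @param C Cost values.
#' @param gamma Gamma tokens ("scale" = 1 / (d * var(X)), "auto" = 1 / d).
#' @param cv_folds Stratified cross-validation folds (default 5).
#' @return An \code{svm_grid_spec}.
#' @export
svm_grid_spec <- function(kernels = c("rbf", "linear"), C = c(0.1, 1, 10),
                          gamma = c("scale", "auto"), cv_folds = 5) {
  if (!length(kernels) || !length(C) || !length(gamma))
    stop("grids must be non-empty", call. = FALSE)
  kernels <- match.arg(kernels, c("rbf", "linear"), several.ok = TRUE)
  structure(list(kernels = kernels, C = sort(C, decreasing = TRUE),
                 gamma = gamma, cv_folds = as.integer(cv_folds)),
            class = "svm_grid_spec")
}

resolve_gamma <- function(gamma, X) {
  if (is.numeric(gamma)) return(gamma)
  d <- ncol(X)
  switch(gamma,
         scale = 1 / (d * mean((X - mean(X))^2)),
         auto = 1 / d,
         stop("unknown gamma token: ", gamma, call. = FALSE))
}

# one-vs-rest binary SVMs (libsvm via e1071), one per class
fit_ovr_svm <- function(X, y, kernel, C, gamma_num, classes) {
  models <- lapply(classes, function(k) {
    yk <- factor(ifelse(y == k, "pos", "rest"), levels = c("pos", "rest"))
    fit <- e1071::svm(X, yk,
                      kernel = if (kernel == "rbf") "radial" else "linear",
                      cost = C, gamma = gamma_num, scale = FALSE)
    m <- list(SV = fit$SV, coefs = as.numeric(fit$coefs), rho = fit$rho)
    # libsvm orients the binary decision towards whichever class it saw
    # first; flip so positive scores always mean "this class"
    sc <- ovr_decision(list(m), X, kernel, gamma_num)[, 1]
    if (mean(sc[yk == "pos"]) < mean(sc[yk == "rest"])) {
      m$coefs <- -m$coefs
      m$rho <- -m$rho
    }
    m
  })
  names(models) <- classes
  models
}

# kernel-sum decision values computed from the stored dual representation
ovr_decision <- function(models, X, kernel, gamma_num) {
  X <- as.matrix(X)
  scores <- vapply(models, function(m) {
    K <- if (kernel == "rbf") {
      d2 <- outer(rowSums(m$SV^2), rowSums(X^2), "+") - 2 * m$SV %*% t(X)
      exp(-gamma_num * pmax(d2, 0))
    } else {
      m$SV %*% t(X)
    }
    as.numeric(crossprod(K, m$coefs)) - m$rho
  }, numeric(nrow(X)))
  matrix(scores, nrow(X), length(models),
         dimnames = list(NULL, names(models)))
}

#' Grid-searched SVM over standardised feature vectors
#'
#' Evaluates every grid cell by stratified k-fold cross-validated accuracy of
#' a one-vs-rest SVM, refits the best cell on all data, and returns the full
#' results table sorted by accuracy (ties keep the documented grid order).
#' Features are expected already standardised
#' (\code{\link{apply_scaler}}); the scaler may be attached for bookkeeping.
#'
#' @param features n x d standardised feature matrix.
#' @param labels Length-n class labels (>= 2 distinct classes).
#' @param grid An \code{\link{svm_grid_spec}}.
#' @param seed Integer seed for fold assignment.
#' @param scaler Optional \code{feature_scaler} stored on the model.
#' @return A \code{trained_svm}: per-class support vectors, dual
#'   coefficients, rho, the resolved gamma, kernel, C, the CV results table
#'   and the class order.
#' @export
grid_search_svm <- function(features, labels, grid = svm_grid_spec(),
                            seed = 42, scaler = NULL) {
  X <- as.matrix(features)
  y <- as.character(labels)
  classes <- sort(unique(y))
  if (length(classes) < 2)
    stop("need at least two classes", call. = FALSE)
  cells <- do.call(rbind, lapply(grid$kernels, function(k)
    expand.grid(kernel = k, C = grid$C, gamma = grid$gamma,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  folds <- integer(length(y))
  with_seed(seed, {
    for (k in classes) {
      idx <- which(y == k)
      folds[idx] <- rep_len(seq_len(grid$cv_folds),
                            length(idx))[sample.int(length(idx))]
    }
  })
  acc <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    correct <- 0L
    for (f in seq_len(grid$cv_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || !any(!tr)) next
      gnum <- resolve_gamma(cells$gamma[ci], X[tr, , drop = FALSE])
      mods <- fit_ovr_svm(X[tr, , drop = FALSE], y[tr], cells$kernel[ci],
                          cells$C[ci], gnum, classes)
      sc <- ovr_decision(mods, X[!tr, , drop = FALSE], cells$kernel[ci], gnum)
      pred <- classes[max.col(sc, ties.method = "first")]
      correct <- correct + sum(pred == y[!tr])
    }
    acc[ci] <- correct / length(y)
  }
  results <- cbind(cells, accuracy = acc)
  results <- results[order(-results$accuracy, seq_len(nrow(results))), ]
  rownames(results) <- NULL
  best <- results[1, ]
  gnum <- resolve_gamma(best$gamma, X)
  models <- fit_ovr_svm(X, y, best$kernel, best$C, gnum, classes)
  structure(list(models = models, kernel = best$kernel, C = best$C,
                 gamma = gnum, gamma_token = best$gamma, classes = classes,
                 results = results, scaler = scaler),
            class = "trained_svm")
}

#' SVM prediction from the stored dual representation
#'
#' Decision values are recomputed directly as the kernel sum
#' \eqn{\sum_i \alpha_i y_i K(x_i, x) - \rho} from the stored support
#' vectors, dual coefficients, gamma and bias -- one score per class
#' (one-vs-rest), with the predicted label the argmax. Features must already
#' be standardised with the model's scaler.
#'
#' @param model A \code{\link{grid_search_svm}} result.
#' @param features Matrix of standardised feature vectors.
#' @return List with \code{labels} (character) and \code{scores}
#'   (n x n_classes matrix).
#' @export
svm_predict <- function(model, features) {
  X <- as.matrix(features)
  if (ncol(X) != ncol(model$models[[1]]$SV))
    stop("feature length (", ncol(X), ") does not match the model (",
         ncol(model$models[[1]]$SV), ")", call. = FALSE)
  sc <- ovr_decision(model$models, X, model$kernel, model$gamma)
  list(labels = model$classes[max.col(sc, ties.method = "first")], scores = sc)
}
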