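# shared fixtures: everything is generated in code at test time

tiny_unet <- function(seed = 3, input_size = 8) {
  build_unet(unet_config(depth = 2, filters = c(2L, 3L),
                         bottleneck_filters = 4L, input_size = input_size),
             seed = seed)
}

# a clean, jitter-free phantom for exact-geometry checks
clean_spec <- function(image_size = 64, class_label = "CN", gm_thickness = 6,
                       ventricle_radius = 4, seed = 1) {
  phantom_spec(image_size = image_size, class_label = class_label,
               gm_thickness = gm_thickness, gm_intensity = 0.55,
               ventricle_radius = ventricle_radius, noise_sigma = 0,
               jitter = 0, seed = seed)
}

# brute-force 2D "same" convolution with zero padding over one channel set;
# w is a k x k x cin array, x an H x W x cin array
brute_conv2d <- function(x, w, b = 0) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  k <- dim(w)[1]; p <- (k - 1) / 2
  H <- dim(x)[1]; W <- dim(x)[2]
  out <- matrix(b, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (di in seq_len(k)) for (dj in seq_len(k)) for (c in seq_len(dim(x)[3])) {
      ii <- i + di - 1 - p; jj <- j + dj - 1 - p
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, c] * w[di, dj, c]
    }
    out[i, j] <- out[i, j] + acc
  }
  out
}

random_mask <- function(n, p = 0.4) matrix(rbinom(n * n, 1, p), n, n)

# small labelled feature set with well-separated classes
toy_features <- function(n_per_class = 12, d = 2, seed = 7) {
  with_seed <- function(s, code) { set.seed(s); force(code) }
  with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * d, 0, 0.4), ncol = d),
               matrix(rnorm(n_per_class * d, 3, 0.4), ncol = d),
               matrix(rnorm(n_per_class * d, -3, 0.4), ncol = d))
    list(X = X, y = rep(c("AD", "CN", "MCI"), each = n_per_class))
  })
}
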