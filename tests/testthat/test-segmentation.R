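test_that("U-Net configs validate shape constraints", {
  expect_s3_class(unet_config(variant = "vanilla"), "unet_config")
  expect_equal(unet_config(variant = "vanilla")$depth, 4L)
  expect_equal(unet_config(variant = "multilayer")$depth, 3L)
  expect_error(unet_config(depth = 3, input_size = 100), "divisible")
  expect_error(unet_config(depth = 2, filters = c(4L), input_size = 32),
               "one entry per encoder level")
  expect_error(unet_config(depth = 1, filters = 0L, input_size = 32), ">= 1")
})

test_that("the built network maps HxW inputs to single-channel HxW logits", {
  cfg <- unet_config(depth = 3, base_filters = 4, input_size = 32)
  m <- build_unet(cfg, seed = 2)
  lg <- gmstage:::unet_step(m, matrix(runif(32 * 32), 32))$logits
  expect_identical(dim(lg), c(32L, 32L))
  p <- predict_mask(m, matrix(runif(32 * 32), 32), probabilities = TRUE)
  expect_true(all(p > 0 & p < 1))
  expect_error(gmstage:::unet_step(m, matrix(0, 16, 16)), "32x32")
})

test_that("balanced cross-entropy reproduces hand-evaluated cases", {
  # single foreground pixel at p = 0.5 with beta = 0.5: 0.5 * ln 2
  expect_equal(balanced_cross_entropy(matrix(1), matrix(0.5), 0.5),
               0.5 * log(2), tolerance = 1e-12)
  # all-background target with beta = 1 annihilates the only active term
  expect_equal(balanced_cross_entropy(matrix(0, 3, 3), matrix(0.9, 3, 3), 1), 0)
  # perfect prediction is zero up to the clipping epsilon
  y <- random_mask(6)
  expect_lte(balanced_cross_entropy(y, y, 0.5), 2e-7 * abs(log(1e-7)))
  expect_error(balanced_cross_entropy(matrix(1), matrix(0.5), 1.5), "beta")
  expect_error(balanced_cross_entropy(matrix(1), matrix(0.5, 2, 2), 0.5),
               "shapes")
})

test_that("balanced cross-entropy matches a per-pixel brute-force sum", {
  set.seed(8)
  for (beta in c(0.1, 0.5, 0.9)) {
    y <- random_mask(8)
    p <- matrix(runif(64, 0.01, 0.99), 8, 8)
    acc <- 0
    for (i in 1:8) for (j in 1:8)
      acc <- acc - beta * y[i, j] * log(p[i, j]) -
        (1 - beta) * (1 - y[i, j]) * log(1 - p[i, j])
    expect_equal(balanced_cross_entropy(y, p, beta), acc / 64,
                 tolerance = 1e-12)
  }
  # beta = 0.5 is half the unweighted binary cross-entropy
  y <- random_mask(8); p <- matrix(runif(64, 0.01, 0.99), 8, 8)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(balanced_cross_entropy(y, p, 0.5), bce / 2, tolerance = 1e-12)
})

test_that("dice loss reproduces its degenerate and hand cases", {
  ones <- matrix(1, 2, 2)
  expect_equal(dice_loss(ones, ones), 0)
  z <- matrix(0, 2, 2)
  expect_equal(dice_loss(z, z), 0)  # smoothing convention for empty masks
  # |P| = 2, |G| = 3, overlap 2: 1 - (4+1)/(5+1) = 1/6
  g <- matrix(c(1, 1, 1, 0), 2, 2)
  p <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_loss(g, p), 1 / 6, tolerance = 1e-12)
  expect_error(dice_loss(g, matrix(0, 3, 3)), "shapes")
})

test_that("the segmentation metric battery matches brute-force confusion counts", {
  g <- matrix(0, 4, 4); g[1, 1:3] <- 1
  p <- matrix(0, 4, 4); p[1, 1:2] <- 1  # P subset of G, |P|=2, |G|=3
  m <- evaluate_segmentation(p, g)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$dice, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$iou, 2 / 3)
  expect_equal(m$accuracy, 15 / 16)
  # identity and disjoint extremes
  id <- evaluate_segmentation(g, g)
  expect_true(all(unlist(id) == 1))
  comp <- evaluate_segmentation(1 - g, g)
  expect_equal(comp$dice, 0)
  expect_equal(comp$iou, 0)
  expect_equal(comp$precision, 0)
  expect_equal(comp$recall, 0)
  expect_error(evaluate_segmentation(matrix(2, 2, 2), matrix(0, 2, 2)),
               "0 and 1")
})

test_that("Dice equals F1 and the Dice-IoU identity holds on random masks", {
  set.seed(10)
  for (t in 1:60) {
    a <- random_mask(8, runif(1, 0.1, 0.9))
    b <- random_mask(8, runif(1, 0.1, 0.9))
    m <- evaluate_segmentation(a, b)
    expect_equal(m$dice, m$f1, tolerance = 1e-12)
    expect_lte(m$iou, m$dice + 1e-12)
    expect_equal(m$dice, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
  }
})

test_that("mask prediction thresholds probabilities as documented", {
  m <- tiny_unet(seed = 6)
  img <- matrix(runif(64), 8, 8)
  pm <- predict_mask(m, img)
  expect_true(all(pm %in% c(0, 1)))
  expect_true(all(predict_mask(m, img, threshold = 0) == 1))
  p <- predict_mask(m, img, probabilities = TRUE)
  expect_identical((p >= 0.5) * 1, predict_mask(m, img))
})

test_that("training overfits a single phantom and is seed-deterministic", {
  sp <- phantom_spec(image_size = 32, class_label = "CN", gm_thickness = 3,
                     gm_intensity = 0.55, ventricle_radius = 2,
                     noise_sigma = 0.01, jitter = 0, seed = 2)
  s <- generate_phantom(sp)
  cfg <- unet_config(depth = 2, base_filters = 8, input_size = 32)
  m <- build_unet(cfg, seed = 1)
  tc <- seg_train_config(learning_rate = 1e-3, batch_size = 1, epochs = 150,
                         seed = 1)
  tr <- train_segmenter(m, list(s$image), list(s$gm_mask),
                        list(s$image), list(s$gm_mask), tc)
  expect_gte(tr$best_val_dice, 0.99)
  expect_equal(nrow(tr$history), 150)
  # determinism: a second run from the same seed reproduces the loss curve
  tc2 <- seg_train_config(learning_rate = 1e-3, batch_size = 1, epochs = 3,
                          seed = 5)
  h1 <- train_segmenter(build_unet(cfg, seed = 1), list(s$image),
                        list(s$gm_mask), list(s$image), list(s$gm_mask),
                        tc2)$history
  h2 <- train_segmenter(build_unet(cfg, seed = 1), list(s$image),
                        list(s$gm_mask), list(s$image), list(s$gm_mask),
                        tc2)$history
  expect_identical(h1, h2)
})

test_that("training rejects empty data and non-binary masks", {
  m <- tiny_unet()
  expect_error(train_segmenter(m, list(), list(), list(), list()), "empty")
  img <- matrix(runif(64), 8, 8)
  expect_error(train_segmenter(m, list(img), list(img), list(img), list(img)),
               "binary")
  expect_error(seg_train_config(learning_rate = 0), "learning_rate")
  expect_error(seg_train_config(beta = 1.5), "beta")
})
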