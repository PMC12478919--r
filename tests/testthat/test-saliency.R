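test_that("linear-model saliency equals the analytic |w| up to normalisation", {
  set.seed(1)
  w <- matrix(rnorm(64), 8, 8)
  mod <- linear_scorer(list(AD = w, CN = -w, MCI = 2 * w))
  img <- matrix(runif(64), 8, 8)
  s <- compute_saliency(mod, img, "AD")
  expect_equal(unclass(s), abs(w) / max(abs(w)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(max(s), 1)
  expect_true(all(s >= 0))
  # invariant to adding a constant to all class scores (bias shift)
  mod2 <- linear_scorer(list(AD = w, CN = -w, MCI = 2 * w), bias = c(5, 5, 5))
  expect_equal(compute_saliency(mod2, img, "AD"), s)
  expect_error(compute_saliency(mod, img, "XX"), "unknown class")
})

test_that("non-differentiable models are refused with a pointer to the head path", {
  toy <- toy_features()
  svm <- grid_search_svm(toy$X, toy$y,
                         svm_grid_spec(kernels = "linear", C = 1,
                                       gamma = "auto", cv_folds = 2))
  expect_error(compute_saliency(svm, matrix(0, 8, 8), "AD"),
               "not differentiable")
})

test_that("classifier saliency has the input shape, is in [0,1] with max 1", {
  bb <- conv_backbone(out_channels = 8, input_size = 32, n_stages = 2,
                      seed = 2)
  hd <- multi_scale_head(8, multi_scale_config(branch_channels = 8), seed = 2)
  model <- gm_classifier(bb, hd)
  img <- matrix(runif(32 * 32), 32)
  s <- compute_saliency(model, img, "MCI")
  expect_identical(dim(s), c(32L, 32L))
  expect_gte(min(s), 0)
  expect_equal(max(s), 1)
})

test_that("classifier saliency matches central differences of the class score", {
  bb <- conv_backbone(out_channels = 4, input_size = 16, n_stages = 2,
                      seed = 3)
  hd <- multi_scale_head(4, multi_scale_config(branch_channels = 4), seed = 3)
  img <- matrix(runif(256), 16, 16)
  score <- function(im) {
    gmstage:::head_forward(hd, extract_features(bb, im))$logits[1]
  }
  # raw gradient before normalisation
  bfw <- gmstage:::backbone_forward(bb, img)
  fmap <- array(bfw$fmap, c(bfw$h, bfw$h, 4))
  hfw <- gmstage:::head_forward(hd, fmap)
  hbw <- gmstage:::head_backward(hd, hfw$cache, c(1, 0, 0))
  g <- gmstage:::backbone_backward(bb, bfw$cache, hbw$gfmap)
  eps <- 1e-4
  for (i in sample(256, 5)) {
    i2 <- img; i2[i] <- i2[i] + eps
    i3 <- img; i3[i] <- i3[i] - eps
    gnum <- (score(i2) - score(i3)) / (2 * eps)
    expect_equal(g[i], gnum, tolerance = max(1e-4, 1e-3 * abs(gnum)))
  }
})

test_that("Gaussian blur preserves total mass of interior-supported maps", {
  s <- matrix(0, 64, 64)
  s[28:36, 28:36] <- runif(81)
  b <- blur_saliency(s, sigma = 2)
  expect_identical(dim(b), dim(s))
  expect_lt(abs(sum(b) - sum(s)) / sum(s), 0.01)
  expect_identical(blur_saliency(s, sigma = 0), s)
})

test_that("overlays tint only the class colour channel over the gray slice", {
  img <- matrix(runif(64), 8, 8)
  zero <- matrix(0, 8, 8)
  # no blur, no edges, zero saliency: exactly the replicated grayscale
  rgb <- render_overlay(zero, img, "CN", blur_sigma = 0, edge_on = FALSE)
  expect_equal(rgb, array(rep(as.numeric(img), 3), c(8, 8, 3)))
  # AD saliency lands in the red channel only
  s <- matrix(runif(64), 8, 8)
  rgb2 <- render_overlay(s, img, "AD", blur_sigma = 0, edge_on = FALSE)
  expect_false(isTRUE(all.equal(rgb2[, , 1], img)))
  expect_equal(rgb2[, , 2], img)
  expect_equal(rgb2[, , 3], img)
  expect_true(all(rgb2 >= 0 & rgb2 <= 1))
  # MCI is blue, CN is green
  expect_false(isTRUE(all.equal(
    render_overlay(s, img, "MCI", blur_sigma = 0, edge_on = FALSE)[, , 3],
    img)))
  expect_error(render_overlay(s, img, "XX"), "unknown class")
  expect_error(render_overlay(matrix(0, 4, 4), img, "AD"), "shapes")
})

test_that("quadrant quantification matches a brute-force double loop", {
  # one-pixel quadrants
  r <- region_quantification(list(matrix(c(1, 0, 0, 0), 2, 2)), "AD")
  expect_equal(unlist(r[r$class == "AD", 2:5], use.names = FALSE),
               c(1, 0, 0, 0))
  # uniform maps give four equal cells
  r2 <- region_quantification(list(matrix(0.3, 6, 6), matrix(0.3, 6, 6)),
                              c("CN", "CN"))
  expect_equal(unlist(r2[r2$class == "CN", 2:5], use.names = FALSE),
               rep(0.3, 4))
  # 30 random maps per class against an explicit pixel/sample loop
  set.seed(8)
  maps <- replicate(90, matrix(runif(64), 8, 8), simplify = FALSE)
  labs <- rep(c("AD", "MCI", "CN"), each = 30)
  r3 <- region_quantification(maps, labs)
  for (k in c("AD", "MCI", "CN")) {
    sel <- which(labs == k)
    acc <- matrix(0, 2, 2); cnt <- 0
    for (i in sel) for (qi in 1:2) for (qj in 1:2) {
      rows <- (qi - 1) * 4 + 1:4; cols <- (qj - 1) * 4 + 1:4
      acc[qi, qj] <- acc[qi, qj] + mean(maps[[i]][rows, cols])
    }
    acc <- acc / length(sel)
    got <- unlist(r3[r3$class == k, 2:5], use.names = FALSE)
    expect_equal(got, c(acc[1, 1], acc[1, 2], acc[2, 1], acc[2, 2]),
                 tolerance = 1e-9)
    # equal-area quadrants: cell mean equals the class's global mean
    expect_equal(mean(got), mean(vapply(maps[sel], mean, numeric(1))),
                 tolerance = 1e-12)
  }
  # an absent class is reported missing, not zero
  r4 <- region_quantification(maps[1:30], rep("AD", 30))
  expect_true(all(is.na(unlist(r4[r4$class == "CN", 2:5]))))
})

test_that("region tables serialise with the documented CSV header", {
  r <- region_quantification(list(matrix(0.2, 4, 4)), "AD")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_region_table(r, path)
  got <- read.csv(path, check.names = FALSE)
  expect_identical(names(got),
                   c("Class", "Region 1", "Region 2", "Region 3", "Region 4"))
})
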