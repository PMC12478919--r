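test_that("backbone feature maps honour the channel and stride contract", {
  bb <- conv_backbone(out_channels = 16, input_size = 32, n_stages = 3,
                      seed = 1)
  fm <- extract_features(bb, matrix(runif(32 * 32), 32))
  expect_identical(dim(fm), c(4L, 4L, 16L))  # spatial = input / 2^3
  expect_error(extract_features(bb, matrix(0, 16, 16)), "32x32")
  bb2 <- conv_backbone(out_channels = 8, input_size = 16, n_stages = 2)
  expect_identical(dim(extract_features(bb2, matrix(0, 16, 16))), c(4L, 4L, 8L))
})

test_that("the multi-scale head concatenates three branches of fixed length", {
  hd <- multi_scale_head(4, multi_scale_config(branch_channels = 128), seed = 2)
  fmap <- array(runif(8 * 8 * 4), c(8, 8, 4))
  v <- multi_scale_forward(hd, fmap)
  expect_length(v, 3 * 128)
  expect_true(all(is.finite(v)))
  # zero weights and biases annihilate the output
  hz <- hd
  for (t in 1:3) {
    hz$params$branches[[t]]$W[] <- 0
    hz$params$branches[[t]]$b[] <- 0
  }
  expect_equal(multi_scale_forward(hz, fmap), rep(0, 384))
  expect_error(multi_scale_forward(hd, array(0, c(8, 8, 5))), "channels")
  expect_error(multi_scale_config(kernel_sizes = c(3, 4, 5)), "odd")
  expect_error(multi_scale_config(kernel_sizes = c(3, 5)), "length 3")
})

test_that("a single 3x3 branch equals a hand-computed convolution chain", {
  cfg <- multi_scale_config(kernel_sizes = 3, branch_channels = 1,
                            leaky_slope = 0.01, dropout_rate = 0)
  hd <- multi_scale_head(1, cfg, seed = 3)
  w <- matrix(c(0.5, -1, 0.25, 2, 1, -0.5, 0, 0.75, -0.25), 3, 3)
  hd$params$branches[[1]]$W <- matrix(as.numeric(w), 9, 1)
  hd$params$branches[[1]]$b <- 0.1
  x <- matrix(seq(0.1, 1.6, by = 0.1), 4, 4)
  # independent oracle: brute-force conv, leaky relu, 2x2 max pool, mean
  conv <- brute_conv2d(x, array(w, c(3, 3, 1)), 0.1)
  act <- ifelse(conv > 0, conv, 0.01 * conv)
  pooled <- c(max(act[1:2, 1:2]), max(act[3:4, 1:2]),
              max(act[1:2, 3:4]), max(act[3:4, 3:4]))
  expect_equal(multi_scale_forward(hd, array(x, c(4, 4, 1))),
               mean(pooled), tolerance = 1e-12)
})

test_that("head training minimises cross-entropy from the uniform start", {
  set.seed(4)
  ds <- generate_dataset(10, image_size = 32, seed = 21)
  imgs <- lapply(ds$samples, function(s) s$image * s$gm_mask)
  labs <- ds$manifest$label
  bb <- conv_backbone(out_channels = 8, input_size = 32, n_stages = 2,
                      seed = 1)
  hd <- multi_scale_head(8, multi_scale_config(branch_channels = 8), seed = 1)
  # zero final layer: softmax is uniform, per-sample loss is ln 3
  hd$params$fc$W[] <- 0
  hd$params$fc$b[] <- 0
  fw <- gmstage:::head_forward(hd, extract_features(bb, imgs[[1]]))
  expect_equal(-log(fw$probs[1]), log(3), tolerance = 1e-12)
  th <- train_head(bb, hd, imgs, labs,
                   clf_train_config(learning_rate = 3e-3, epochs = 4,
                                    seed = 2))
  expect_equal(nrow(th$history), 4)
  expect_lt(tail(th$history$loss, 1), log(3))
  th2 <- train_head(bb, hd, imgs, labs,
                    clf_train_config(learning_rate = 3e-3, epochs = 4,
                                     seed = 2))
  expect_identical(th$history, th2$history)
  expect_error(train_head(bb, hd, list(), character(0)), "empty")
  expect_error(train_head(bb, hd, imgs, rep("XX", length(imgs))), "labels")
})

test_that("the feature scaler standardises training columns and spares constants", {
  set.seed(5)
  X <- cbind(matrix(rnorm(60, 5, 3), 20), const = rep(2, 20))
  sc <- fit_scaler(X)
  Z <- apply_scaler(sc, X)
  expect_equal(unname(colMeans(Z)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(Z[, 1:3], 2, var)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(Z[, 4]), rep(0, 20))  # centred, scale-1 convention
  expect_equal(sc$scale[[4]], 1)
})

test_that("grid search returns the best cell with deterministic tie-breaking", {
  toy <- toy_features()
  sc <- fit_scaler(toy$X)
  Z <- apply_scaler(sc, toy$X)
  # singleton grid: that cell is returned
  g1 <- grid_search_svm(Z, toy$y,
                        svm_grid_spec(kernels = "rbf", C = 1,
                                      gamma = "auto", cv_folds = 3))
  expect_equal(g1$kernel, "rbf")
  expect_equal(g1$C, 1)
  expect_equal(nrow(g1$results), 1)
  # linear cells with gamma scale/auto are computationally identical:
  # the tie resolves to the first documented order (scale first)
  g2 <- grid_search_svm(Z, toy$y,
                        svm_grid_spec(kernels = "linear", C = 1,
                                      gamma = c("scale", "auto"),
                                      cv_folds = 3))
  expect_equal(g2$results$accuracy[1], g2$results$accuracy[2])
  expect_equal(g2$gamma_token, "scale")
  g2b <- grid_search_svm(Z, toy$y,
                         svm_grid_spec(kernels = "linear", C = 1,
                                       gamma = c("scale", "auto"),
                                       cv_folds = 3))
  expect_identical(g2$results, g2b$results)
  # full default grid: table is sorted descending and covers 12 cells
  g3 <- grid_search_svm(Z, toy$y, svm_grid_spec(cv_folds = 3))
  expect_equal(nrow(g3$results), 12)
  expect_true(!is.unsorted(rev(g3$results$accuracy)))
  expect_error(grid_search_svm(Z, rep("AD", nrow(Z)),
                               svm_grid_spec(cv_folds = 3)), "two classes")
})

test_that("decision values equal the explicit kernel sum and e1071's own values", {
  X <- rbind(c(0, 0), c(0, 1), c(3, 3), c(3, 4))
  y <- c("AD", "AD", "CN", "CN")
  m <- grid_search_svm(X, y, svm_grid_spec(kernels = "rbf", C = 1, gamma = 1,
                                           cv_folds = 2))
  pr <- svm_predict(m, X)
  expect_identical(pr$labels, y)
  # brute-force evaluation of the stored dual representation
  mod <- m$models[["AD"]]
  for (r in 1:4) {
    s <- sum(mod$coefs * exp(-1 * colSums((t(mod$SV) - X[r, ])^2))) - mod$rho
    expect_equal(unname(pr$scores[r, "AD"]), unname(s), tolerance = 1e-10)
  }
  # cross-check against libsvm's own decision values (orientation included)
  yk <- factor(ifelse(y == "AD", "pos", "rest"), levels = c("pos", "rest"))
  ref <- e1071::svm(X, yk, kernel = "radial", gamma = 1, cost = 1,
                    scale = FALSE)
  dv <- attr(predict(ref, X, decision.values = TRUE), "decision.values")[, 1]
  sgn <- if (cor(dv, pr$scores[, "AD"]) < 0) -1 else 1
  expect_equal(pr$scores[, "AD"], sgn * unname(dv), tolerance = 1e-10)
  # linearly separable two-point set with the linear kernel
  m2 <- grid_search_svm(rbind(c(-1, 0), c(1, 0), c(-1, .1), c(1, .1)),
                        c("AD", "CN", "AD", "CN"),
                        svm_grid_spec(kernels = "linear", C = 1,
                                      gamma = "auto", cv_folds = 2))
  p2 <- svm_predict(m2, rbind(c(-1, 0), c(1, 0)))
  expect_identical(p2$labels, c("AD", "CN"))
  # three-class scores come back as an n x 3 matrix
  toy <- toy_features()
  m3 <- grid_search_svm(toy$X, toy$y,
                        svm_grid_spec(kernels = "rbf", C = 1,
                                      gamma = "scale", cv_folds = 2))
  expect_identical(dim(svm_predict(m3, toy$X)$scores),
                   c(nrow(toy$X), 3L))
  expect_error(svm_predict(m3, matrix(0, 2, 5)), "feature length")
})

test_that("the classification report matches brute-force per-class counts", {
  # construct predictions realising confusion rows AD:[8,1,1] CN:[0,9,1] MCI:[2,0,8]
  truth <- rep(c("AD", "CN", "MCI"), each = 10)
  pred <- c(rep("AD", 8), "CN", "MCI",
            rep("CN", 9), "MCI",
            "AD", "AD", rep("MCI", 8))
  r <- evaluate_classifier(pred, truth)
  expect_equal(r$accuracy, 25 / 30)
  expect_equal(r$confusion["AD", ], c(AD = 8L, CN = 1L, MCI = 1L))
  pc <- r$per_class
  expect_equal(pc$precision[pc$class == "AD"], 8 / 10)
  expect_equal(pc$recall[pc$class == "AD"], 8 / 10)
  expect_equal(sum(diag(r$confusion)) / sum(r$confusion), r$accuracy)
  # identity and floor cases
  perf <- evaluate_classifier(truth, truth)
  expect_equal(perf$accuracy, 1)
  expect_true(all(perf$per_class$f1 == 1))
  expect_true(all(r$confusion >= 0))
  wrong <- evaluate_classifier(c("AD", "CN"), c("CN", "AD"))
  expect_equal(wrong$accuracy, 0)
  expect_error(evaluate_classifier(c("AD", "XX"), c("AD", "CN")), "unknown")
  expect_error(evaluate_classifier("AD", c("AD", "CN")), "length")
})

test_that("per-class F1 is the harmonic mean of precision and recall", {
  set.seed(6)
  for (t in 1:20) {
    truth <- sample(c("AD", "CN", "MCI"), 30, replace = TRUE)
    pred <- sample(c("AD", "CN", "MCI"), 30, replace = TRUE)
    if (length(unique(truth)) < 3) next
    pc <- evaluate_classifier(pred, truth)$per_class
    for (i in 1:3) {
      p <- pc$precision[i]; r <- pc$recall[i]
      expect_equal(pc$f1[i], if (p + r == 0) 0 else 2 * p * r / (p + r),
                   tolerance = 1e-12)
    }
  }
})

test_that("one-vs-rest ROC reproduces rank-counted AUCs and Youden thresholds", {
  # positives {0.9, 0.4} vs negatives {0.6, 0.1}: 3 of 4 pairs ordered -> 0.75
  sc <- cbind(AD = c(0.9, 0.4, 0.6, 0.1), CN = 0, MCI = 0)
  labs <- c("AD", "AD", "CN", "CN")
  r <- roc_one_vs_rest(sc, labs)
  expect_equal(r$AD$auc, 0.75)
  # perfectly separated scores
  sc2 <- cbind(AD = c(5, 4, 1, 0), CN = 0, MCI = 0)
  expect_equal(roc_one_vs_rest(sc2, labs)$AD$auc, 1)
  # uninformative identical scores
  sc3 <- cbind(AD = rep(1, 4), CN = 0, MCI = 0)
  expect_equal(roc_one_vs_rest(sc3, labs)$AD$auc, 0.5)
  # AUC equals the normalised Mann-Whitney pair count on random score sets
  set.seed(7)
  for (t in 1:20) {
    s <- runif(12)
    lab <- sample(c("AD", "CN"), 12, replace = TRUE, prob = c(.5, .5))
    if (!any(lab == "AD") || !any(lab == "CN")) next
    r <- roc_one_vs_rest(cbind(AD = s, CN = 0, MCI = 0), lab)
    pos <- s[lab == "AD"]; neg <- s[lab != "AD"]
    mw <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(r$AD$auc, mw, tolerance = 1e-12)
  }
  # a class absent from the labels reports a missing AUC, not zero
  r4 <- roc_one_vs_rest(cbind(AD = runif(4), CN = runif(4), MCI = runif(4)),
                        c("AD", "AD", "CN", "CN"))
  expect_true(is.na(r4$MCI$auc))
  expect_error(roc_one_vs_rest(cbind(AD = NA, CN = 0, MCI = 0), "AD"),
               "finite")
})

test_that("the McNemar test matches hand counts and the stats reference", {
  # b = 10, c = 2: (b-c)^2/(b+c) = 64/12
  truth <- rep("AD", 12)
  a <- rep("AD", 12)                     # A always correct
  b <- c(rep("CN", 10), rep("AD", 2))    # B wrong on 10
  truth2 <- c(truth, rep("CN", 2)); a2 <- c(a, rep("AD", 2)); b2 <- c(b, "CN", "CN")
  r <- mcnemar_test(a2, b2, truth2)
  expect_equal(r$b, 10); expect_equal(r$c, 2)
  expect_equal(r$statistic, 64 / 12, tolerance = 1e-12)
  ref <- stats::mcnemar.test(table(a2 == truth2, b2 == truth2),
                             correct = FALSE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  # symmetric discordance: each classifier right where the other is wrong
  truth3 <- rep("AD", 10)
  a3 <- c(rep("AD", 5), rep("CN", 5))
  b3 <- c(rep("CN", 5), rep("AD", 5))
  r2 <- mcnemar_test(a3, b3, truth3)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  expect_error(mcnemar_test("AD", c("AD", "CN"), c("AD", "CN")), "length")
})
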