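#' Pipeline configuration
#'
#' Assembles the configuration of the four-phase run: phantom generation,
#' preprocessing/split, segmentation training, hybrid classification and
#' saliency analysis. Defaults follow the reference training recipe where one
#' exists (Adam, balanced cross-entropy, batch size 8 for segmentation and 32
#' for the head, SVM grid over \{rbf, linear\} x C \{0.1, 1, 10\} x gamma
#' \{scale, auto\}, seeds 42..46 with five repeats) and otherwise use desk
#' -scale problem sizes (64-pixel phantoms, tens of samples per class) chosen
#' so a full repeat runs in minutes on one CPU. A YAML file and/or named
#' overrides replace any default; overrides win over the file.
#'
#' @param file Optional YAML config path.
#' @param ... Named overrides of top-level fields or nested lists
#'   (\code{seg}, \code{clf}, \code{xai} are merged field-wise).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- list(
    output_root = "runs",
    image_size = 64, n_per_class = 30, noise_sigma = 0.02, jitter = 0.08,
    split = list(train = 0.6, val = 0.2, test = 0.2),
    augment_target = NULL,
    seeds = 42:46, run_repeats = 5,
    seg = list(variant = "multilayer", base_filters = 8, epochs = 3,
               learning_rate = 1e-3, batch_size = 8, loss = "balanced_bce",
               beta = "auto"),
    clf = list(backbone_channels = 32, branch_channels = 32, epochs = 3,
               learning_rate = 1e-3, batch_size = 32, cv_folds = 3,
               single_scale = FALSE, use_segmentation = TRUE,
               end_to_end = FALSE),
    xai = list(blur_sigma = 2, n_per_class = 5))
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
          !is.null(names(upd[[nm]])))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  if (!is.null(file)) cfg <- merge_into(cfg, yaml::read_yaml(file))
  dots <- list(...)
  if (length(dots)) cfg <- merge_into(cfg, dots)
  if (anyDuplicated(cfg$seeds)) stop("seeds must be unique", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

log_line <- function(logfile, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  message(msg)
  cat(msg, "\n", file = logfile, append = TRUE)
}

pipeline_stages <- function() {
  c("generate", "preprocess", "train-seg", "train-clf", "evaluate", "explain")
}

#' Run the four-phase pipeline
#'
#' Executes the requested stages in canonical order (generate, preprocess,
#' train-seg, train-clf, evaluate, explain), repeated over
#' \code{config$run_repeats} seeds, and writes every artifact -- config
#' snapshot, structured log, per-seed metric rows, mean +/- sd summary and
#' region saliency table -- under a timestamped run directory. A stage whose
#' input is missing fails with an error naming the producing stage.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param stages Subset of the canonical stages to run.
#' @return Invisibly, a \code{pipeline_report}: list(metrics, summary,
#'   region_table, dir, counts).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = pipeline_stages()) {
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  run_dir <- file.path(config$output_root,
                       format(Sys.time(), "run-%Y%m%d-%H%M%S"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(run_dir, "config.yaml"))
  logfile <- file.path(run_dir, "log.txt")
  seeds <- config$seeds[seq_len(min(config$run_repeats, length(config$seeds)))]
  rows <- list()
  region_tables <- list()
  n_generated <- 0L
  for (seed in seeds) {
    log_line(logfile, "seed ", seed, ": stages ", paste(stages, collapse = ","))
    set_global_seeds(seed)
    ds <- NULL; seg <- NULL; clf <- NULL
    if ("generate" %in% stages) {
      ds <- generate_dataset(config$n_per_class, image_size = config$image_size,
                             noise_sigma = config$noise_sigma,
                             jitter = config$jitter, seed = seed,
                             dir = if (isTRUE(config$write_samples))
                               file.path(run_dir, paste0("data-seed", seed))
                             else NULL)
      n_generated <- n_generated + length(ds$samples)
      log_line(logfile, "generated ", length(ds$samples), " phantoms")
    }
    if (!length(setdiff(stages, "generate"))) next
    if (is.null(ds))
      stop("stage '", setdiff(stages, "generate")[1],
           "' needs phantoms produced by stage 'generate'", call. = FALSE)
    if ("preprocess" %in% stages) {
      ds <- split_dataset(ds, split_ratios(config$split$train,
                                           config$split$val,
                                           config$split$test), seed = seed)
      for (i in seq_along(ds$samples))
        ds$samples[[i]]$image <- normalize_slice(ds$samples[[i]]$image,
                                                 config$image_size)
      log_line(logfile, "split: ",
               paste(names(table(ds$manifest$split)),
                     table(ds$manifest$split), collapse = " "))
    }
    sel <- function(split) which(ds$manifest$split == split)
    imgs <- function(ix) lapply(ds$samples[ix], `[[`, "image")
    gmm <- function(ix) lapply(ds$samples[ix], `[[`, "gm_mask")
    brm <- function(ix) lapply(ds$samples[ix], `[[`, "brain_mask")
    labs <- function(ix) ds$manifest$label[ix]
    seg_metrics_row <- list()
    if ("train-seg" %in% stages) {
      if (!"preprocess" %in% stages)
        stop("stage 'train-seg' needs the split produced by stage ",
             "'preprocess'", call. = FALSE)
      masks_of <- if (config$seg$variant == "vanilla") brm else gmm
      scfg <- seg_train_config(learning_rate = config$seg$learning_rate,
                               batch_size = config$seg$batch_size,
                               epochs = config$seg$epochs,
                               loss = config$seg$loss, beta = config$seg$beta,
                               seed = seed)
      ucfg <- unet_config(variant = config$seg$variant,
                          base_filters = config$seg$base_filters,
                          input_size = config$image_size)
      model <- build_unet(ucfg, seed = seed)
      seg <- train_segmenter(model, imgs(sel("train")), masks_of(sel("train")),
                             imgs(sel("val")), masks_of(sel("val")), scfg)
      test_dice <- mean(vapply(sel("test"), function(i)
        dice_coefficient(predict_mask(seg, ds$samples[[i]]$image),
                         masks_of(i)[[1]]), numeric(1)))
      seg_metrics_row <- list(val_dice = seg$best_val_dice,
                              test_dice = test_dice)
      log_line(logfile, sprintf("segmenter: val dice %.4f, test dice %.4f",
                                seg$best_val_dice, test_dice))
    }
    clf_metrics_row <- list()
    report <- NULL
    clf_inputs <- NULL
    if ("train-clf" %in% stages) {
      if (!"preprocess" %in% stages)
        stop("stage 'train-clf' needs the split produced by stage ",
             "'preprocess'", call. = FALSE)
      if (config$clf$use_segmentation && is.null(seg))
        stop("stage 'train-clf' with use_segmentation needs the model ",
             "produced by stage 'train-seg'", call. = FALSE)
      clf_inputs <- function(ix) {
        lapply(ds$samples[ix], function(s) {
          if (config$clf$use_segmentation)
            s$image * predict_mask(seg, s$image)
          else s$image
        })
      }
      backbone <- conv_backbone(out_channels = config$clf$backbone_channels,
                                input_size = config$image_size, seed = seed)
      mcfg <- multi_scale_config(
        kernel_sizes = if (config$clf$single_scale) 3L else c(3L, 5L, 7L),
        branch_channels = config$clf$branch_channels)
      head0 <- multi_scale_head(config$clf$backbone_channels, mcfg, seed = seed)
      ccfg <- clf_train_config(learning_rate = config$clf$learning_rate,
                               batch_size = config$clf$batch_size,
                               epochs = config$clf$epochs, seed = seed)
      tr_in <- clf_inputs(sel("train"))
      tr_lab <- labs(sel("train"))
      if (!is.null(config$augment_target)) {
        # class-wise expansion of the training split only (no leakage)
        aug_in <- list(); aug_lab <- character(0)
        for (k in stage_classes()) {
          ik <- which(tr_lab == k)
          ex <- augment_to_count(tr_in[ik],
                                 augment_policy(seed = seed + match(k, stage_classes())),
                                 target = config$augment_target)
          aug_in <- c(aug_in, ex)
          aug_lab <- c(aug_lab, rep(k, length(ex)))
        }
        tr_in <- aug_in; tr_lab <- aug_lab
        log_line(logfile, "augmented training split to ",
                 config$augment_target, " per class")
      }
      th <- train_head(backbone, head0, tr_in, tr_lab, ccfg)
      clf <- list(backbone = backbone, head = th)
      if (config$clf$end_to_end) {
        test_probs <- t(vapply(clf_inputs(sel("test")), function(im)
          head_forward(th$head, extract_features(backbone, im))$probs,
          numeric(3)))
        pred <- stage_classes()[max.col(test_probs, ties.method = "first")]
        report <- evaluate_classifier(pred, labs(sel("test")))
        clf$scores <- test_probs
      } else {
        ftr <- head_features(backbone, th, tr_in)
        scaler <- fit_scaler(ftr)
        svm <- grid_search_svm(apply_scaler(scaler, ftr), tr_lab,
                               svm_grid_spec(cv_folds = config$clf$cv_folds),
                               seed = seed, scaler = scaler)
        fte <- apply_scaler(scaler, head_features(backbone, th,
                                                  clf_inputs(sel("test"))))
        pr <- svm_predict(svm, fte)
        report <- evaluate_classifier(pr$labels, labs(sel("test")))
        clf$svm <- svm
        clf$scores <- pr$scores
      }
      log_line(logfile, sprintf("classifier: test accuracy %.4f",
                                report$accuracy))
    }
    if ("evaluate" %in% stages && !is.null(report)) {
      roc <- roc_one_vs_rest(clf$scores, labs(sel("test")))
      clf_metrics_row <- c(list(accuracy = report$accuracy),
                           as.list(setNames(report$per_class$f1,
                                            paste0("f1_",
                                                   report$per_class$class))),
                           as.list(setNames(vapply(roc, `[[`, numeric(1),
                                                   "auc"),
                                            paste0("auc_", names(roc)))))
    } else if (!is.null(report)) {
      clf_metrics_row <- list(accuracy = report$accuracy)
    }
    if ("explain" %in% stages && !is.null(clf)) {
      model <- gm_classifier(clf$backbone, clf$head)
      ix_test <- sel("test")
      pick <- unlist(lapply(stage_classes(), function(k) {
        kk <- ix_test[labs(ix_test) == k]
        head(kk, config$xai$n_per_class)
      }))
      smaps <- lapply(pick, function(i)
        compute_saliency(model, clf_inputs(i)[[1]], ds$manifest$label[i]))
      region_tables[[length(region_tables) + 1L]] <-
        region_quantification(smaps, labs(pick))
      gm_ratio <- mean(vapply(seq_along(pick), function(t) {
        s <- smaps[[t]]; g <- ds$samples[[pick[t]]]$gm_mask
        bgm <- ds$samples[[pick[t]]]$brain_mask
        mean(s[g == 1]) / max(mean(s[bgm == 0]), 1e-12)
      }, numeric(1)))
      clf_metrics_row$saliency_gm_bg_ratio <- gm_ratio
      log_line(logfile, sprintf("saliency GM/background ratio %.2f", gm_ratio))
    }
    rows[[length(rows) + 1L]] <-
      as.data.frame(c(list(seed = seed), seg_metrics_row, clf_metrics_row))
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else data.frame(seed = seeds)
  num <- setdiff(names(metrics), "seed")
  summary <- if (length(num)) {
    data.frame(metric = num,
               mean = vapply(num, function(c) mean(metrics[[c]]), numeric(1)),
               sd = vapply(num, function(c)
                 if (nrow(metrics) > 1) sd(metrics[[c]]) else 0, numeric(1)))
  } else data.frame(metric = character(), mean = numeric(), sd = numeric())
  write.csv(metrics, file.path(run_dir, "metrics.csv"), row.names = FALSE)
  write.csv(summary, file.path(run_dir, "summary.csv"), row.names = FALSE)
  if (length(region_tables))
    write_region_table(region_tables[[1]],
                       file.path(run_dir, "region_saliency.csv"))
  jsonlite::write_json(list(metrics = metrics, summary = summary),
                       file.path(run_dir, "metrics.json"), digits = NA)
  report <- structure(list(metrics = metrics, summary = summary,
                           region_table = if (length(region_tables))
                             region_tables[[1]] else NULL,
                           dir = run_dir, counts = n_generated),
                      class = "pipeline_report")
  log_line(logfile, "done")
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline run in ", x$dir, "\n", sep = "")
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
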