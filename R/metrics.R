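#' Dice similarity coefficient of two binary masks
#'
#' \eqn{2|P \cap G| / (|P| + |G|)}; two empty masks score 1 by convention.
#'
#' @param pred,truth Binary matrices of identical shape.
#' @return Scalar in [0, 1].
#' @export
dice_coefficient <- function(pred, truth) {
  check_binary_pair(pred, truth)
  s <- sum(pred) + sum(truth)
  if (s == 0) return(1)
  2 * sum(pred * truth) / s
}

check_binary_pair <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("mask shapes differ", call. = FALSE)
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must contain only 0 and 1", call. = FALSE)
  invisible(TRUE)
}

#' Segmentation metric battery
#'
#' Computes Dice, IoU (Jaccard), accuracy, precision, recall and F1 from the
#' pixel-level confusion counts, with the mask foreground as the positive
#' class. For binary masks Dice and F1 coincide, and
#' Dice = 2 IoU / (1 + IoU).
#'
#' Degenerate conventions: with an empty union, Dice = IoU = 1; precision
#' (recall) is 1 when there are no predicted (true) positives.
#'
#' @param pred Predicted binary mask.
#' @param truth Ground-truth binary mask of the same shape.
#' @return A \code{seg_metrics} list with fields dice, iou, accuracy,
#'   precision, recall, f1.
#' @export
evaluate_segmentation <- function(pred, truth) {
  check_binary_pair(pred, truth)
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  dice <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  iou <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  prec <- if (tp + fp == 0) 1 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  structure(list(dice = dice, iou = iou,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 precision = prec, recall = rec, f1 = f1),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("dice %.4f  iou %.4f  acc %.4f  prec %.4f  rec %.4f  f1 %.4f\n",
              x$dice, x$iou, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

stage_classes <- function() c("AD", "CN", "MCI")

#' Multi-class classification report
#'
#' Overall accuracy, a 3x3 confusion matrix (true classes as rows) and
#' one-vs-rest precision / recall / F1 per diagnostic class.
#'
#' @param pred_labels,true_labels Equal-length character/factor vectors over
#'   \{AD, CN, MCI\}.
#' @return A \code{classification_report} list with fields accuracy,
#'   confusion (matrix), and per_class (data.frame class/precision/recall/f1).
#' @export
evaluate_classifier <- function(pred_labels, true_labels) {
  cls <- stage_classes()
  pred_labels <- as.character(pred_labels)
  true_labels <- as.character(true_labels)
  if (length(pred_labels) != length(true_labels))
    stop("label vectors differ in length", call. = FALSE)
  bad <- setdiff(unique(c(pred_labels, true_labels)), cls)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cm <- table(factor(true_labels, cls), factor(pred_labels, cls))
  cm <- matrix(as.integer(cm), 3, 3, dimnames = list(true = cls, pred = cls))
  per <- do.call(rbind, lapply(cls, function(k) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = k, precision = prec, recall = rec, f1 = f1)
  }))
  structure(list(accuracy = sum(diag(cm)) / sum(cm), confusion = cm,
                 per_class = per),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f\n", x$accuracy))
  print(x$confusion)
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' One-vs-rest ROC curves, AUCs and optimal thresholds
#'
#' For each diagnostic class, sweeps every distinct score as a decision
#' threshold (sample positive iff score >= threshold), traces TPR vs FPR,
#' integrates the AUC by the trapezoidal rule and picks the optimal operating
#' threshold maximising TPR - FPR (Youden); ties resolve to the smallest
#' qualifying threshold. A class absent from \code{true_labels} yields an NA
#' AUC rather than 0.
#'
#' @param scores n x 3 matrix of per-class decision scores (columns AD, CN,
#'   MCI in that order, or named).
#' @param true_labels Length-n labels over \{AD, CN, MCI\}.
#' @return A named list per class: \code{curve} (data.frame threshold / fpr /
#'   tpr), \code{auc}, \code{optimal_threshold}.
#' @export
roc_one_vs_rest <- function(scores, true_labels) {
  cls <- stage_classes()
  scores <- as.matrix(scores)
  if (ncol(scores) != 3) stop("scores must have 3 columns", call. = FALSE)
  if (is.null(colnames(scores))) colnames(scores) <- cls
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  true_labels <- as.character(true_labels)
  out <- lapply(cls, function(k) {
    pos <- true_labels == k
    if (!any(pos)) {
      return(list(curve = NULL, auc = NA_real_, optimal_threshold = NA_real_))
    }
    s <- scores[, k]
    th <- c(Inf, sort(unique(s), decreasing = TRUE))
    tpr <- vapply(th, function(t) mean(s[pos] >= t), numeric(1))
    fpr <- if (all(pos)) rep(0, length(th))
           else vapply(th, function(t) mean(s[!pos] >= t), numeric(1))
    auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
    j <- tpr - fpr
    best <- which(j == max(j))
    opt <- min(th[best])
    list(curve = data.frame(threshold = th, fpr = fpr, tpr = tpr),
         auc = auc, optimal_threshold = opt)
  })
  names(out) <- cls
  out
}

#' McNemar paired test between two classifiers
#'
#' Counts the discordant pairs b (A correct, B wrong) and c (A wrong, B
#' correct) and refers \eqn{(b - c)^2 / (b + c)} to a chi-squared distribution
#' with one degree of freedom (upper tail). No continuity correction by
#' default; set \code{correct = TRUE} for Edwards' corrected statistic.
#' When b + c = 0 the statistic is 0 and p = 1.
#'
#' @param preds_a,preds_b Predicted labels of the two classifiers.
#' @param truth True labels, same length.
#' @param correct Apply the continuity correction.
#' @return List with statistic, p_value, b, c.
#' @export
mcnemar_test <- function(preds_a, preds_b, truth, correct = FALSE) {
  if (length(preds_a) != length(truth) || length(preds_b) != length(truth))
    stop("prediction and truth vectors differ in length", call. = FALSE)
  ca <- preds_a == truth
  cb <- preds_b == truth
  b <- sum(ca & !cb)
  c <- sum(!ca & cb)
  if (b + c == 0) {
    stat <- 0; p <- 1
  } else {
    stat <- if (correct) (abs(b - c) - 1)^2 / (b + c) else (b - c)^2 / (b + c)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, b = b, c = c)
}
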