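#' Combined backbone + head classifier handle
#'
#' Bundles a frozen backbone with a trained multi-scale head into one
#' differentiable classifier, the object saliency maps are computed through.
#'
#' @param backbone A \code{\link{conv_backbone}}.
#' @param head A \code{multi_scale_head} or \code{trained_head}.
#' @return A \code{gm_classifier}.
#' @export
gm_classifier <- function(backbone, head) {
  if (inherits(head, "trained_head")) head <- head$head
  structure(list(backbone = backbone, head = head), class = "gm_classifier")
}

#' Linear pixel scorer (analytic reference model)
#'
#' A classifier whose class score is the inner product of the image with a
#' per-class weight map: score_k = sum(W_k * x) + b_k. Its input gradient is
#' the weight map itself, which makes it the closed-form reference for
#' saliency checks.
#'
#' @param weights List of weight matrices, one per class (named by class).
#' @param bias Numeric vector of per-class offsets (default 0).
#' @return A \code{linear_scorer}.
#' @export
linear_scorer <- function(weights, bias = numeric(length(weights))) {
  structure(list(weights = weights, bias = bias), class = "linear_scorer")
}

#' Gradient saliency map
#'
#' The absolute gradient of the pre-softmax score of \code{target_class} with
#' respect to every input pixel (maximum over input channels when the input
#' has several), normalised by its maximum so the brightest pixel is exactly
#' 1; an all-zero map stays zero. Gradients flow through the differentiable
#' softmax head, never the SVM (whose sign decision has zero gradient almost
#' everywhere) -- passing a \code{trained_svm} raises an error pointing to
#' the head-based path.
#'
#' @param model A \code{\link{gm_classifier}} or \code{\link{linear_scorer}}.
#' @param image Input slice.
#' @param target_class Class whose score is differentiated ("AD", "CN",
#'   "MCI"; for a linear scorer, any of its weight names/indices).
#' @return A \code{saliency_map} matrix in [0, 1], same shape as the input.
#' @export
compute_saliency <- function(model, image, target_class) {
  UseMethod("compute_saliency")
}

#' @export
compute_saliency.gm_classifier <- function(model, image, target_class) {
  ci <- match(target_class, stage_classes())
  if (is.na(ci)) stop("unknown class: ", target_class, call. = FALSE)
  bfw <- backbone_forward(model$backbone, image)
  fmap <- array(bfw$fmap, dim = c(bfw$h, bfw$h, model$backbone$channels))
  hfw <- head_forward(model$head, fmap, training = FALSE)
  dlogits <- numeric(3); dlogits[ci] <- 1
  hbw <- head_backward(model$head, hfw$cache, dlogits)
  g <- backbone_backward(model$backbone, bfw$cache, hbw$gfmap)
  normalize_saliency(abs(g))
}

#' @export
compute_saliency.linear_scorer <- function(model, image, target_class) {
  w <- model$weights[[target_class]]
  if (is.null(w)) stop("unknown class: ", target_class, call. = FALSE)
  normalize_saliency(abs(w))
}

#' @export
compute_saliency.default <- function(model, image, target_class) {
  stop("model of class <", paste(class(model), collapse = "/"),
       "> is not differentiable with respect to input pixels; compute ",
       "saliency through the softmax head path (see gm_classifier())",
       call. = FALSE)
}

normalize_saliency <- function(s) {
  m <- max(s)
  out <- if (m > 0) s / m else s
  structure(out, class = c("saliency_map", class(out)))
}

#' Gaussian-blur a saliency map
#'
#' Discrete Gaussian smoothing (sigma in pixels); sigma 0 is the identity.
#' For maps supported away from the border, total mass is preserved.
#'
#' @param saliency Saliency matrix.
#' @param sigma Blur standard deviation in pixels.
#' @return Blurred matrix of the same shape.
#' @export
blur_saliency <- function(saliency, sigma = 2) {
  if (sigma <= 0) return(unclass(saliency))
  as.matrix(EBImage::gblur(matrix(as.numeric(saliency), nrow(saliency)),
                           sigma = sigma))
}

sobel_edges <- function(image) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(image, kx))
  gy <- as.matrix(EBImage::filter2(image, t(kx)))
  e <- sqrt(gx^2 + gy^2)
  m <- max(e)
  if (m > 0) e / m else e
}

#' Render a class-coloured saliency overlay
#'
#' Blurs the saliency map, optionally mixes in a Sobel edge map of the
#' gray-matter slice, and alpha-blends the result into the class colour
#' channel over the grayscale slice: red for AD, blue for MCI, green for CN
#' (only that channel carries the tint). With zero blur, no edges and a zero
#' map, the output is exactly the grayscale slice replicated to RGB.
#'
#' @param saliency Saliency map (same shape as the slice).
#' @param image Grayscale slice in [0, 1].
#' @param predicted_class "AD", "MCI" or "CN".
#' @param blur_sigma Gaussian sigma in pixels (default 2).
#' @param edge_on Mix a Sobel edge map into the overlay intensity.
#' @param alpha Blend weight of the tint (default 0.6).
#' @param edge_weight Weight of the edge map when \code{edge_on} (default 0.3).
#' @return H x W x 3 RGB array in [0, 1].
#' @export
render_overlay <- function(saliency, image, predicted_class, blur_sigma = 2,
                           edge_on = TRUE, alpha = 0.6, edge_weight = 0.3) {
  if (!all(dim(saliency) == dim(image)))
    stop("saliency and image shapes differ", call. = FALSE)
  chan <- c(AD = 1L, CN = 2L, MCI = 3L)[predicted_class]
  if (is.na(chan)) stop("unknown class: ", predicted_class, call. = FALSE)
  s <- blur_saliency(saliency, blur_sigma)
  if (edge_on) s <- (1 - edge_weight) * s + edge_weight * sobel_edges(image)
  s <- pmin(pmax(s, 0), 1)
  rgb <- array(rep(as.numeric(image), 3), dim = c(dim(image), 3))
  rgb[, , chan] <- image + alpha * s * (1 - image)
  rgb
}

#' Quadrant-level saliency quantification
#'
#' Divides every map into four equal quadrants (Region 1 = top-left,
#' 2 = top-right, 3 = bottom-left, 4 = bottom-right) and averages the
#' saliency per quadrant over all samples of each class. For equal-area
#' quadrants the mean of the four cells equals a class's global mean
#' saliency. Classes with no samples are reported as missing (NA), not zero.
#'
#' @param maps List of saliency matrices (all the same shape).
#' @param labels Class label per map.
#' @return A \code{region_saliency_table} data.frame with columns class and
#'   region1..region4, rows ordered AD, MCI, CN.
#' @export
region_quantification <- function(maps, labels) {
  stopifnot(length(maps) == length(labels))
  dm <- dim(maps[[1]])
  for (m in maps)
    if (!all(dim(m) == dm)) stop("maps must share one shape", call. = FALSE)
  h2 <- dm[1] %/% 2L; w2 <- dm[2] %/% 2L
  quad_means <- function(m) c(
    mean(m[seq_len(h2), seq_len(w2)]),
    mean(m[seq_len(h2), (w2 + 1):dm[2]]),
    mean(m[(h2 + 1):dm[1], seq_len(w2)]),
    mean(m[(h2 + 1):dm[1], (w2 + 1):dm[2]]))
  labels <- as.character(labels)
  rows <- lapply(c("AD", "MCI", "CN"), function(k) {
    sel <- which(labels == k)
    if (!length(sel))
      return(data.frame(class = k, region1 = NA_real_, region2 = NA_real_,
                        region3 = NA_real_, region4 = NA_real_))
    qm <- rowMeans(vapply(maps[sel], quad_means, numeric(4)))
    data.frame(class = k, region1 = qm[1], region2 = qm[2], region3 = qm[3],
               region4 = qm[4])
  })
  structure(do.call(rbind, rows),
            class = c("region_saliency_table", "data.frame"))
}

#' Write a region saliency table as CSV
#'
#' Columns: Class, Region 1..Region 4.
#'
#' @param table A \code{\link{region_quantification}} result.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_region_table <- function(table, path) {
  out <- table
  names(out) <- c("Class", "Region 1", "Region 2", "Region 3", "Region 4")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
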