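#' Select the central fraction of axial slices
#'
#' Keeps the middle block of slices -- the ones carrying most brain anatomy --
#' from a stack of \code{n_slices} axial slices. The kept count is
#' \code{round(fraction * n_slices)} (round half up, minimum 1) and the block
#' is centred with \code{start = floor((n_slices - k) / 2)}.
#'
#' @param n_slices Number of slices in the volume (>= 1).
#' @param fraction Fraction to keep, in (0, 1].
#' @return Zero-based contiguous slice indices \code{start:(start + k - 1)}
#'   (zero-based to match on-disk slice numbering; add 1 to index an R array).
#' @export
select_middle_slices <- function(n_slices, fraction = 0.4) {
  if (n_slices < 1) stop("n_slices must be >= 1", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  k <- max(1L, as.integer(floor(fraction * n_slices + 0.5)))
  start <- (n_slices - k) %/% 2L
  seq.int(start, start + k - 1L)
}

#' Extract the central axial slices of a NIfTI volume
#'
#' Reads a volume (axial = third axis), applies
#' \code{\link{select_middle_slices}} and returns the slices as matrices.
#'
#' @param path Path to a NIfTI file.
#' @param fraction Central fraction to keep.
#' @return List of 2D matrices.
#' @export
load_volume_slices <- function(path, fraction = 0.4) {
  vol <- RNifti::readNifti(path)
  vol <- as.array(vol)
  if (length(dim(vol)) < 3) stop("expected a 3D volume", call. = FALSE)
  idx <- select_middle_slices(dim(vol)[3], fraction)
  lapply(idx + 1L, function(i) vol[, , i])
}

#' Resize and min--max normalize a slice
#'
#' Bilinearly resizes to \code{out_size} x \code{out_size} and rescales
#' intensities to [0, 1] per slice. A constant slice maps to all zeros
#' (degenerate-range convention avoiding division by zero).
#'
#' @param image Non-empty numeric matrix.
#' @param out_size Output side length in pixels (default 224).
#' @return \code{out_size} x \code{out_size} matrix in [0, 1].
#' @export
normalize_slice <- function(image, out_size = 224) {
  if (is.null(dim(image)) || any(dim(image) == 0) || length(image) == 0)
    stop("empty image", call. = FALSE)
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  if (nrow(img) != out_size || ncol(img) != out_size)
    img <- EBImage::resize(img, w = out_size, h = out_size)
  rng <- range(img)
  if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
  else matrix(0, out_size, out_size)
}

#' Augmentation policy
#'
#' Random small rotations (uniform in +/- \code{rotation_limit} degrees)
#' composed with isotropic zoom (uniform scale in
#' \code{1 +/- zoom_limit}), applied rotation-first with bilinear
#' interpolation and zero padding.
#'
#' @param rotation_limit Max absolute rotation in degrees (>= 0; default 7).
#' @param zoom_limit Max absolute zoom fraction in [0, 1) (default 0.10).
#' @param seed Integer seed for the transform draws.
#' @return An \code{augment_policy} object.
#' @export
augment_policy <- function(rotation_limit = 7, zoom_limit = 0.10, seed = 42) {
  if (rotation_limit < 0) stop("rotation_limit must be >= 0", call. = FALSE)
  if (zoom_limit < 0 || zoom_limit >= 1)
    stop("zoom_limit must lie in [0, 1)", call. = FALSE)
  structure(list(rotation_limit = rotation_limit, zoom_limit = zoom_limit,
                 seed = as.integer(seed)),
            class = "augment_policy")
}

# rotate about the centre, keep dimensions, zero background
rot_zoom <- function(img, angle, zoom) {
  S <- nrow(img)
  out <- EBImage::rotate(img, angle, output.dim = c(S, S), bg.col = 0)
  out <- as.matrix(out)
  S2 <- max(2L, as.integer(round(S * zoom)))
  z <- as.matrix(EBImage::resize(out, w = S2, h = S2))
  if (S2 == S) return(z)
  if (S2 > S) {                        # zoom in: centre crop
    o <- (S2 - S) %/% 2L
    z[o + seq_len(S), o + seq_len(S)]
  } else {                             # zoom out: centre pad with zeros
    p <- matrix(0, S, S)
    o <- (S - S2) %/% 2L
    p[o + seq_len(S2), o + seq_len(S2)] <- z
    p
  }
}

#' Expand an image list to a target count by augmentation
#'
#' Returns all originals followed by \code{target - n} randomly transformed
#' copies; source images are cycled in order, so the output is deterministic
#' for a fixed policy seed. Sub-sampling is refused.
#'
#' @param images Non-empty list of equally sized matrices.
#' @param policy An \code{\link{augment_policy}}.
#' @param target Desired output count (>= length(images)).
#' @return List of \code{target} matrices; the first \code{length(images)}
#'   elements are the untouched originals.
#' @export
augment_to_count <- function(images, policy = augment_policy(), target) {
  n <- length(images)
  if (n < 1) stop("need at least one image", call. = FALSE)
  if (target < n)
    stop("target (", target, ") below image count (", n,
         "); augmentation never subsamples", call. = FALSE)
  out <- images
  if (target == n) return(out)
  with_seed(policy$seed, {
    for (t in seq_len(target - n)) {
      src <- images[[(t - 1L) %% n + 1L]]
      angle <- runif(1, -policy$rotation_limit, policy$rotation_limit)
      zoom <- runif(1, 1 - policy$zoom_limit, 1 + policy$zoom_limit)
      out[[n + t]] <- rot_zoom(src, angle, zoom)
    }
  })
  out
}

#' Train/validation/test split ratios
#'
#' @param train,val,test Fractions, each in (0, 1), summing to 1 (within
#'   1e-9). Default 60/20/20.
#' @return A \code{split_ratios} object.
#' @export
split_ratios <- function(train = 0.6, val = 0.2, test = 0.2) {
  r <- c(train = train, val = val, test = test)
  if (any(r <= 0) || any(r >= 1))
    stop("each ratio must lie strictly in (0, 1)", call. = FALSE)
  if (abs(sum(r) - 1) > 1e-9)
    stop("ratios must sum to 1", call. = FALSE)
  structure(as.list(r), class = "split_ratios")
}

#' Stratified dataset split
#'
#' Assigns each manifest record to train / val / test, stratified by class.
#' Within each class the val and test sizes are \code{round(ratio * n)}
#' (round half up) and the remainder goes to train; assignment order is a
#' seeded permutation, so the split is reproducible and no record lands in
#' two splits.
#'
#' @param dataset A \code{phantom_dataset}, or a manifest data.frame with a
#'   \code{label} column.
#' @param ratios A \code{\link{split_ratios}}.
#' @param seed Integer seed.
#' @return Same type as the input, with the \code{split} column filled.
#' @export
split_dataset <- function(dataset, ratios = split_ratios(), seed = 42) {
  stopifnot(inherits(ratios, "split_ratios"))
  man <- if (inherits(dataset, "phantom_dataset")) dataset$manifest else dataset
  if (!"label" %in% names(man)) stop("manifest lacks a label column", call. = FALSE)
  if (min(table(man$label)) < 3)
    stop("every class needs >= 3 records to split", call. = FALSE)
  rhu <- function(x) floor(x + 0.5)
  man$split <- NA_character_
  with_seed(seed, {
    for (k in unique(man$label)) {
      idx <- which(man$label == k)
      n <- length(idx)
      n_val <- rhu(ratios$val * n)
      n_test <- rhu(ratios$test * n)
      idx <- idx[sample.int(n)]
      man$split[idx[seq_len(n - n_val - n_test)]] <- "train"
      man$split[idx[n - n_val - n_test + seq_len(n_val)]] <- "val"
      man$split[idx[n - n_test + seq_len(n_test)]] <- "test"
    }
  })
  if (inherits(dataset, "phantom_dataset")) {
    dataset$manifest <- man
    dataset
  } else {
    man
  }
}
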