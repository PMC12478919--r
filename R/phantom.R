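#' Specification of a synthetic brain-slice phantom
#'
#' A phantom is a square grayscale slice built from five concentric tissue
#' regions -- background, skull rim, CSF ring, gray-matter (GM) annulus and
#' white-matter (WM) core -- plus a central elliptical ventricle filled with
#' CSF. The two imaging biomarkers of disease stage are encoded
#' geometrically: the GM annulus thins and dims from CN to MCI to AD, and the
#' ventricle enlarges. Radii are expressed in pixels at the requested image
#' size.
#'
#' @param image_size Side length in pixels (>= 32; default 224).
#' @param class_label One of "AD", "MCI", "CN".
#' @param gm_thickness Mean GM annulus thickness in pixels (> 0).
#' @param gm_intensity GM intensity in [0, 1].
#' @param ventricle_radius Ventricle semi-major axis in pixels.
#' @param noise_sigma Additive Gaussian noise SD (>= 0); the image is clipped
#'   back to [0, 1].
#' @param jitter Per-sample multiplicative shape jitter, as a fraction of each
#'   radius (uniform in +/- jitter).
#' @param seed Integer seed; an identical spec always yields an identical
#'   sample.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(image_size = 224, class_label = c("CN", "MCI", "AD"),
                         gm_thickness = 9, gm_intensity = 0.6,
                         ventricle_radius = 6, noise_sigma = 0.02,
                         jitter = 0.08, seed = 1) {
  class_label <- match.arg(class_label)
  if (image_size < 32) stop("image_size must be >= 32", call. = FALSE)
  if (gm_thickness <= 0) stop("gm_thickness must be > 0", call. = FALSE)
  if (gm_intensity < 0 || gm_intensity > 1)
    stop("gm_intensity must lie in [0, 1]", call. = FALSE)
  if (ventricle_radius <= 0) stop("ventricle_radius must be > 0", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 class_label = class_label, gm_thickness = gm_thickness,
                 gm_intensity = gm_intensity,
                 ventricle_radius = ventricle_radius,
                 noise_sigma = noise_sigma, jitter = jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default per-class phantom parameters
#'
#' Class means at the 224-pixel reference scale -- GM thickness 9 / 7 / 5 px
#' and ventricle radii 6 / 8 / 11 px for CN / MCI / AD, GM intensity
#' 0.60 / 0.55 / 0.50 -- scaled linearly to \code{image_size}. The separation
#' is deliberately strong so that small training runs converge on a CPU.
#'
#' @param image_size Target image side in pixels.
#' @return data.frame with columns label, gm_thickness, gm_intensity,
#'   ventricle_radius.
#' @export
phantom_class_table <- function(image_size = 224) {
  s <- image_size / 224
  data.frame(label = c("CN", "MCI", "AD"),
             gm_thickness = c(9, 7, 5) * s,
             gm_intensity = c(0.60, 0.55, 0.50),
             ventricle_radius = c(6, 8, 11) * s,
             stringsAsFactors = FALSE)
}

# fixed tissue intensities and reference radii (224-pixel scale)
phantom_geometry <- function() {
  list(skull_outer = 100, skull_inner = 94, csf_inner = 88,
       v_background = 0, v_skull = 0.95, v_csf = 0.12, v_wm = 0.80)
}

#' Generate one phantom sample
#'
#' Rasterises the concentric geometry of \code{\link{phantom_spec}} into a
#' grayscale image plus exact ground-truth masks. The brain mask covers
#' everything inside the skull (CSF ring, GM, WM, ventricle); the GM mask is
#' the annulus between the WM core and the CSF ring, so the GM mask is always
#' a subset of the brain mask. Shape jitter rescales the ring radii, the GM
#' thickness and the ventricle axis by independent uniform factors, and
#' offsets the centre.
#'
#' @param spec A \code{phantom_spec}.
#' @return A \code{phantom_sample}: list(image, brain_mask, gm_mask, label,
#'   meta = spec), all matrices \code{image_size} square.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    S <- spec$image_size
    sc <- S / 224
    geo <- phantom_geometry()
    jit <- function() 1 + runif(1, -spec$jitter, spec$jitter)
    f_ring <- jit()
    thick <- spec$gm_thickness * jit()
    rv <- spec$ventricle_radius * jit()
    r_brain_ref <- geo$skull_inner * sc
    off <- runif(2, -1, 1) * spec$jitter * r_brain_ref
    cx <- (S + 1) / 2 + off[1]
    cy <- (S + 1) / 2 + off[2]
    xs <- matrix(rep(seq_len(S), each = S), S, S)   # column index
    ys <- matrix(rep(seq_len(S), times = S), S, S)  # row index
    r <- sqrt((xs - cx)^2 + (ys - cy)^2)
    r_sk_o <- geo$skull_outer * sc * f_ring
    r_sk_i <- geo$skull_inner * sc * f_ring
    r_csf_i <- geo$csf_inner * sc * f_ring
    r_gm_i <- r_csf_i - thick
    vent <- ((xs - cx) / rv)^2 + ((ys - cy) / (0.7 * rv))^2 <= 1
    img <- matrix(geo$v_background, S, S)
    img[r <= r_sk_o] <- geo$v_skull
    img[r <= r_sk_i] <- geo$v_csf
    img[r <= r_csf_i] <- spec$gm_intensity
    img[r <= r_gm_i] <- geo$v_wm
    img[vent & r <= r_gm_i] <- geo$v_csf
    brain_mask <- (r <= r_sk_i) * 1
    gm_mask <- (r <= r_csf_i & r > r_gm_i) * 1
    if (spec$noise_sigma > 0) {
      img <- img + matrix(rnorm(S * S, sd = spec$noise_sigma), S, S)
      img <- pmin(pmax(img, 0), 1)
    }
    structure(list(image = img, brain_mask = brain_mask, gm_mask = gm_mask,
                   label = spec$class_label, meta = spec),
              class = "phantom_sample")
  })
}

#' Generate a labelled phantom dataset
#'
#' Draws \code{n_per_class} samples per diagnostic class using the class
#' parameter table. Per-sample seeds are \code{seed + record index}, so the
#' dataset is reproducible record-by-record and independent of generation
#' order. Optionally writes samples and a manifest to disk
#' (\code{\link{write_phantom_dataset}}).
#'
#' @param n_per_class Samples per class (>= 1).
#' @param class_table Per-class parameters as from
#'   \code{\link{phantom_class_table}}.
#' @param image_size Image side in pixels.
#' @param noise_sigma,jitter Shared noise / jitter settings.
#' @param seed Global integer seed.
#' @param dir Optional output directory; when given, PNG images, PNG masks,
#'   a CSV manifest and a JSON parameter sidecar are written there.
#' @return A \code{phantom_dataset}: list(samples, manifest, seed).
#' @export
generate_dataset <- function(n_per_class, class_table = NULL, image_size = 224,
                             noise_sigma = 0.02, jitter = 0.08, seed = 42,
                             dir = NULL) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  if (is.null(class_table)) class_table <- phantom_class_table(image_size)
  n_per_class <- as.integer(n_per_class)
  samples <- vector("list", 3L * n_per_class)
  rec <- 0L
  rows <- list()
  for (k in seq_len(nrow(class_table))) {
    for (i in seq_len(n_per_class)) {
      rec <- rec + 1L
      sp <- phantom_spec(image_size = image_size,
                         class_label = class_table$label[k],
                         gm_thickness = class_table$gm_thickness[k],
                         gm_intensity = class_table$gm_intensity[k],
                         ventricle_radius = class_table$ventricle_radius[k],
                         noise_sigma = noise_sigma, jitter = jitter,
                         seed = seed + rec)
      samples[[rec]] <- generate_phantom(sp)
      rows[[rec]] <- data.frame(id = sprintf("s%04d", rec),
                                label = class_table$label[k],
                                seed = seed + rec, split = NA_character_,
                                stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  ds <- structure(list(samples = samples, manifest = manifest, seed = seed),
                  class = "phantom_dataset")
  if (!is.null(dir)) write_phantom_dataset(ds, dir)
  ds
}

#' Write a phantom dataset to disk
#'
#' Images as 8-bit grayscale PNG, masks as PNG with values \{0, 255\}, the
#' manifest as CSV (id, image_path, brain_mask_path, gm_mask_path, label,
#' split) and the generation parameters as a JSON sidecar.
#'
#' @param dataset A \code{phantom_dataset}.
#' @param dir Output directory (created if missing).
#' @param format "png" or "nifti" for the image files (masks stay PNG).
#' @return Invisibly, the manifest with path columns filled in.
#' @export
write_phantom_dataset <- function(dataset, dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  ext <- if (format == "png") ".png" else ".nii.gz"
  man$image_path <- file.path(dir, paste0(man$id, "_img", ext))
  man$brain_mask_path <- file.path(dir, paste0(man$id, "_brain.png"))
  man$gm_mask_path <- file.path(dir, paste0(man$id, "_gm.png"))
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    if (format == "png") png::writePNG(s$image, man$image_path[i])
    else RNifti::writeNifti(RNifti::asNifti(s$image), man$image_path[i])
    png::writePNG(s$brain_mask, man$brain_mask_path[i])
    png::writePNG(s$gm_mask, man$gm_mask_path[i])
  }
  man <- man[, c("id", "image_path", "brain_mask_path", "gm_mask_path",
                 "label", "split", "seed")]
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  meta <- dataset$samples[[1]]$meta
  jsonlite::write_json(
    list(seed = dataset$seed, n = length(dataset$samples),
         image_size = meta$image_size, noise_sigma = meta$noise_sigma,
         jitter = meta$jitter),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Read a phantom dataset written by \code{\link{write_phantom_dataset}}
#'
#' @param dir Dataset directory containing \code{manifest.csv}.
#' @return A \code{phantom_dataset} (sample \code{meta} fields are not
#'   reconstructed; labels and masks are).
#' @export
read_phantom_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(man)), function(i) {
    read_img <- function(p) {
      if (grepl("\\.png$", p)) {
        m <- png::readPNG(p)
        if (length(dim(m)) == 3) m <- m[, , 1]
        m
      } else {
        as.matrix(RNifti::readNifti(p))
      }
    }
    structure(list(image = read_img(man$image_path[i]),
                   brain_mask = round(read_img(man$brain_mask_path[i])),
                   gm_mask = round(read_img(man$gm_mask_path[i])),
                   label = man$label[i], meta = NULL),
              class = "phantom_sample")
  })
  structure(list(samples = samples, manifest = man, seed = NA_integer_),
            class = "phantom_dataset")
}
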