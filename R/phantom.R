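# Synthetic brain phantom generator. Produces labeled 2-D brain-like
# images with ground-truth lesion masks so that segmentation, feature
# extraction and both classifiers can be exercised and tested without
# patient data. The phantom is an elliptical "skull + brain" with smooth
# tissue texture and paired dark ventricles; a lesion, when present, is a
# radial blob whose boundary irregularity and internal texture
# heterogeneity encode the benign (round, homogeneous) vs malignant
# (irregular, heterogeneous) contrast, and whose sign of intensity
# contrast encodes the modality (T2-like: lesion brighter than tissue;
# T1-like: darker). This is a stand-in for real MR data, not a physical
# simulation.

#' Specification of one synthetic brain phantom
#'
#' Class conventions enforced here: `benign` lesions have
#' `irregularity <= 0.2` and `heterogeneity <= 0.2`; `malignant` lesions
#' have `irregularity >= 0.5` or `heterogeneity >= 0.5`; `normal` images
#' have no lesion.
#'
#' @param class `"normal"`, `"benign"` or `"malignant"`.
#' @param modality `"T2"` (lesion brighter than tissue, default) or
#'   `"T1"` (lesion darker).
#' @param size integer `(H, W)` image size (default `c(256, 256)`).
#' @param lesion_center `(x, y)` zero-based pixel coordinates, or `NULL`
#'   for a seed-determined position inside the brain.
#' @param lesion_radius mean lesion radius in pixels, or `NULL` for
#'   `0.12 * min(H, W)`.
#' @param irregularity boundary irregularity in `[0, 1]`; default 0.1
#'   (benign) / 0.7 (malignant).
#' @param heterogeneity internal texture heterogeneity in `[0, 1]`;
#'   default 0.1 (benign) / 0.6 (malignant).
#' @param contrast_delta absolute lesion-vs-tissue contrast (default 0.3).
#' @param noise_sigma additive Gaussian noise sd (default 0.02).
#' @param seed integer seed; the phantom is deterministic given the spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(class = c("normal", "benign", "malignant"),
                         modality = c("T2", "T1"),
                         size = c(256L, 256L),
                         lesion_center = NULL, lesion_radius = NULL,
                         irregularity = NULL, heterogeneity = NULL,
                         contrast_delta = 0.3, noise_sigma = 0.02,
                         seed = 0L) {
  class <- match.arg(class)
  modality <- match.arg(modality)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 32L))
    stopf("`size` must be (H, W) with both >= 32")
  if (is.null(irregularity))
    irregularity <- switch(class, normal = 0, benign = 0.1, malignant = 0.7)
  if (is.null(heterogeneity))
    heterogeneity <- switch(class, normal = 0, benign = 0.1, malignant = 0.6)
  if (class == "benign" && (irregularity > 0.2 || heterogeneity > 0.2))
    stopf("benign phantoms require irregularity and heterogeneity <= 0.2")
  if (class == "malignant" && irregularity < 0.5 && heterogeneity < 0.5)
    stopf("malignant phantoms require irregularity >= 0.5 or heterogeneity >= 0.5")
  structure(list(class = class, modality = modality, size = size,
                 lesion_center = lesion_center, lesion_radius = lesion_radius,
                 irregularity = irregularity, heterogeneity = heterogeneity,
                 contrast_delta = contrast_delta, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Seed-determined smooth Gaussian random field, standardized to sd 1.
# The blur radius is capped so the kernel fits inside small images.
smooth_field <- function(h, w, sigma) {
  sigma <- min(sigma, (min(h, w) - 3) / 7)
  z <- matrix(stats::rnorm(h * w), h, w)
  f <- EBImage::gblur(EBImage::Image(z), sigma = sigma)
  f <- matrix(as.numeric(EBImage::imageData(f)), h, w)
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

#' Generate a synthetic brain phantom
#'
#' Renders the phantom described by a [phantom_spec()]: elliptical skull
#' and brain with smooth tissue texture and ventricles, an optional
#' lesion with the spec's irregularity/heterogeneity/contrast, light
#' smoothing, and additive Gaussian noise. Deterministic given the spec
#' (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom`: list with `image` (H x W matrix in `[0, 1]`),
#'   `mask` (0/1 ground-truth lesion mask) and `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(class = "malignant", seed = 42))
#' range(ph$image); sum(ph$mask) > 0
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  with_seed(spec$seed, {
    cx <- (w - 1) / 2; cy <- (h - 1) / 2
    rx <- 0.40 * w; ry <- 0.45 * h
    x <- matrix(rep(seq_len(w) - 1, each = h), h, w)
    y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
    e <- ((x - cx) / rx)^2 + ((y - cy) / ry)^2
    brain <- e <= 1
    skull <- e <= 1 & e > 0.88
    tissue_base <- if (spec$modality == "T1") 0.55 else 0.45
    img <- matrix(0.02, h, w)
    tex <- smooth_field(h, w, sigma = 12 * min(h, w) / 256)
    img[brain] <- tissue_base + 0.05 * tex[brain]
    img[skull] <- 0.08            # cortical bone is dark in both sequences
    # paired dark ventricles near the midline
    for (sgn in c(-1, 1)) {
      vx <- cx + sgn * 0.10 * w; vy <- cy - 0.05 * h
      ve <- ((x - vx) / (0.045 * w))^2 + ((y - vy) / (0.14 * h))^2
      img[ve <= 1] <- img[ve <= 1] - 0.15
    }
    mask <- matrix(0, h, w)
    if (spec$class != "normal") {
      R <- spec$lesion_radius
      if (is.null(R)) R <- 0.12 * min(h, w)
      reach <- R * (1 + spec$irregularity)
      ctr <- spec$lesion_center
      if (is.null(ctr)) {
        # sample within the region where the whole lesion fits
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0.15, 0.8)
        ctr <- c(cx + rad * max(rx - reach, 0) * cos(ang),
                 cy + rad * max(ry - reach, 0) * sin(ang))
      }
      fit <- ((ctr[1] - cx) / (rx - reach))^2 + ((ctr[2] - cy) / (ry - reach))^2
      if (rx <= reach || ry <= reach || fit > 1)
        stopf("lesion (center %.0f,%.0f radius %.0f) does not fit inside the brain ellipse",
              ctr[1], ctr[2], R)
      # radial boundary: R * (1 + irregularity * low-order Fourier bumps)
      kk <- 2:6
      amp <- stats::rnorm(length(kk)) / kk
      phs <- stats::runif(length(kk), 0, 2 * pi)
      amp <- 0.6 * amp / max(sum(abs(amp)), 1e-9)
      dx <- x - ctr[1]; dy <- y - ctr[2]
      th <- atan2(dy, dx)
      rb <- R * (1 + spec$irregularity *
                   Reduce(`+`, Map(function(a, k, p) a * cos(k * th + p),
                                   amp, kk, phs)))
      inside <- (dx^2 + dy^2) <= rb^2
      mask[inside] <- 1
      sgn <- if (spec$modality == "T1") -1 else 1
      het_tex <- smooth_field(h, w,
                              sigma = max(1.5, 8 * (1 - spec$heterogeneity)))
      img[inside] <- tissue_base + sgn * spec$contrast_delta +
        spec$heterogeneity * 0.4 * het_tex[inside]
    }
    img <- EBImage::gblur(EBImage::Image(img), sigma = 1)
    img <- matrix(as.numeric(EBImage::imageData(img)), h, w)
    if (spec$noise_sigma > 0)
      img <- img + stats::rnorm(h * w, sd = spec$noise_sigma)
    structure(list(image = clip01(img), mask = mask, spec = spec),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  s <- x$spec
  cat(sprintf("%s %s phantom %dx%d (seed %d), lesion %d px\n",
              s$modality, s$class, s$size[1], s$size[2], s$seed, sum(x$mask)))
  invisible(x)
}

#' Rotate and scale an image (distortion operator)
#'
#' Rotates about the image center by `angle_deg` in `[-180, 180]` and
#' scales about the center by `scale` in `[0.25, 1.5]`, in a single
#' bilinear resampling pass with zero fill. The output keeps the input's
#' shape.
#'
#' @param img numeric matrix.
#' @param angle_deg rotation in degrees, `[-180, 180]`.
#' @param scale scale factor, `[0.25, 1.5]`.
#' @return distorted matrix, same shape.
#' @export
distort <- function(img, angle_deg = 0, scale = 1) {
  check_gray(img)
  if (abs(angle_deg) > 180) stopf("`angle_deg` must be in [-180, 180]")
  if (scale < 0.25 || scale > 1.5) stopf("`scale` must be in [0.25, 1.5]")
  h <- nrow(img); w <- ncol(img)
  xc <- (w - 1) / 2; yc <- (h - 1) / 2
  a <- angle_deg * pi / 180
  cxv <- (rep(seq_len(w) - 1, each = h) - xc) / scale
  cyv <- (rep(seq_len(h) - 1, times = w) - yc) / scale
  sx <- cos(a) * cxv + sin(a) * cyv + xc
  sy <- -sin(a) * cxv + cos(a) * cyv + yc
  matrix(bilinear_sample(img, sx, sy, fill = 0), h, w)
}

#' Generate a labeled phantom dataset
#'
#' Emits exactly the requested per-class train/validation counts, with
#' per-image seeds derived from the master seed so the manifest fully
#' determines every image. Presets reproduce the published
#' tumor-classification splits: `"table1"` (simulated; 9/7 train, 2/2
#' validation), `"table2"` (T2; 18/20, 4/6), `"table3"` (T1; 13/5, 4/2).
#'
#' Benign images draw irregularity and heterogeneity uniformly from
#' `[0.02, 0.2]`, malignant from `[0.5, 0.9]` and `[0.4, 0.8]`; lesion
#' position and radius are also randomized per image.
#'
#' @param preset `NULL` or one of `"table1"`, `"table2"`, `"table3"`
#'   (sets counts and modality; explicit arguments override counts).
#' @param train_benign,train_malignant,val_benign,val_malignant counts.
#' @param normal_train,normal_val counts of lesion-free images (for the
#'   abnormality task; default 0).
#' @param modality `"T2"` or `"T1"`.
#' @param distortion `"none"`, `"rotate"`, or `"rotate+scale"`.
#' @param distort_split which split the distortion policy applies to:
#'   `"validation"` (default), `"all"`, or `"none"`.
#' @param size image size `(H, W)`.
#' @param noise_sigma additive noise sd passed to every phantom.
#' @param seed master seed.
#' @return a `phantom_dataset`: list with `images` (list of matrices),
#'   `masks`, and `manifest` (data frame: id, split, class, modality,
#'   angle, scale, seed).
#' @examples
#' ds <- make_dataset(preset = "table1", seed = 1)
#' table(ds$manifest$split, ds$manifest$class)
#' @export
make_dataset <- function(preset = NULL,
                         train_benign = 0L, train_malignant = 0L,
                         val_benign = 0L, val_malignant = 0L,
                         normal_train = 0L, normal_val = 0L,
                         modality = c("T2", "T1"),
                         distortion = c("none", "rotate", "rotate+scale"),
                         distort_split = c("validation", "all", "none"),
                         size = c(256L, 256L), noise_sigma = 0.02,
                         seed = 0L) {
  distortion_given <- !missing(distortion)
  split_given <- !missing(distort_split)
  distortion <- match.arg(distortion)
  distort_split <- match.arg(distort_split)
  if (!is.null(preset)) {
    p <- switch(preset,
      table1 = list(counts = c(9L, 7L, 2L, 2L), modality = "T2",
                    distortion = "rotate+scale", distort_split = "all"),
      table2 = list(counts = c(18L, 20L, 4L, 6L), modality = "T2"),
      table3 = list(counts = c(13L, 5L, 4L, 2L), modality = "T1"),
      stopf("unknown preset '%s'", preset))
    train_benign <- p$counts[1]; train_malignant <- p$counts[2]
    val_benign <- p$counts[3]; val_malignant <- p$counts[4]
    modality <- p$modality
    if (!distortion_given && !is.null(p$distortion)) distortion <- p$distortion
    if (!split_given && !is.null(p$distort_split))
      distort_split <- p$distort_split
  } else {
    modality <- match.arg(modality)
  }
  counts <- c(normal_train, train_benign, train_malignant,
              normal_val, val_benign, val_malignant)
  if (any(counts < 0L)) stopf("counts must be >= 0")
  man <- data.frame(
    split = rep(c("train", "validation"),
                c(sum(counts[1:3]), sum(counts[4:6]))),
    class = c(rep(c("normal", "benign", "malignant"), counts[1:3]),
              rep(c("normal", "benign", "malignant"), counts[4:6])),
    stringsAsFactors = FALSE)
  n <- nrow(man)
  man$id <- sprintf("img%03d", seq_len(n))
  man$modality <- modality
  man$seed <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  man$angle <- 0; man$scale <- 1
  distorted <- switch(distort_split,
                      none = rep(FALSE, n),
                      all = rep(TRUE, n),
                      validation = man$split == "validation")
  if (distortion == "none") distorted[] <- FALSE
  for (i in which(distorted)) {
    dpar <- with_seed(derive_seed(man$seed[i], 999L), {
      c(stats::runif(1, -180, 180),
        if (distortion == "rotate+scale") stats::runif(1, 0.25, 1.5) else 1)
    })
    man$angle[i] <- dpar[1]; man$scale[i] <- dpar[2]
  }
  images <- vector("list", n); masks <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- man$class[i]
    par <- with_seed(derive_seed(man$seed[i], 1L), {
      if (cls == "benign")
        c(irr = stats::runif(1, 0.02, 0.2), het = stats::runif(1, 0.02, 0.2))
      else if (cls == "malignant")
        c(irr = stats::runif(1, 0.5, 0.9), het = stats::runif(1, 0.4, 0.8))
      else c(irr = 0, het = 0)
    })
    sp <- phantom_spec(class = cls, modality = modality, size = size,
                       irregularity = unname(par["irr"]),
                       heterogeneity = unname(par["het"]),
                       noise_sigma = noise_sigma, seed = man$seed[i])
    ph <- make_phantom(sp)
    img <- ph$image
    if (man$angle[i] != 0 || man$scale[i] != 1)
      img <- distort(img, man$angle[i], man$scale[i])
    images[[i]] <- img
    masks[[i]] <- ph$mask
  }
  man <- man[, c("id", "split", "class", "modality", "angle", "scale", "seed")]
  structure(list(images = images, masks = masks, manifest = man,
                 master_seed = as.integer(seed)),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("phantom dataset: %d images (master seed %d)\n",
              nrow(m), x$master_seed))
  print(table(m$split, m$class))
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' Writes each image (and ground-truth mask) as 8-bit PNG plus a
#' `manifest.csv` describing every image.
#'
#' @param ds a `phantom_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  m <- ds$manifest
  m$path <- file.path(dir, paste0(m$id, ".png"))
  for (i in seq_len(nrow(m))) {
    save_image(ds$images[[i]], m$path[i])
    save_image(ds$masks[[i]], file.path(dir, "masks", paste0(m$id[i], ".png")))
  }
  utils::write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
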