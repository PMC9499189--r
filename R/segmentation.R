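# K-means segmentation of the brain image. Grayscale inputs are
# clustered on intensity; color inputs are first converted to the a*b*
# chromaticity coordinates of CIELAB (D65), dropping lightness, so that
# clusters separate tissue color rather than illumination. The candidate
# tumor mask is the brightest cluster restricted to its largest connected
# component.

#' K-means clustering (Lloyd's algorithm with k-means++ seeding)
#'
#' Deterministic given `(points, k, seed)`. Iteration stops when the
#' maximum center movement falls below `tol` or after `max_iter` passes.
#' If a cluster empties, its center is re-seeded at the point farthest
#' from its assigned center. The within-cluster sum of squares (inertia)
#' is non-increasing across iterations.
#'
#' @param points numeric `n x d` matrix (a vector is taken as 1-D points).
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer seed for the k-means++ initialization.
#' @param max_iter,tol iteration controls.
#' @param init optional `k x d` matrix of initial centers overriding the
#'   k-means++ initialization.
#' @return list with `labels` (1..k), `centers` (`k x d`), `inertia`,
#'   `iterations`, and `inertia_trace` (per-iteration inertia).
#' @examples
#' km <- kmeans_lloyd(c(0, 1, 10, 11), k = 2, seed = 1)
#' km$centers; km$inertia
#' @export
kmeans_lloyd <- function(points, k, seed = 0L, max_iter = 300L, tol = 1e-6,
                         init = NULL) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points); d <- ncol(points)
  k <- as.integer(k)
  if (k < 1L) stopf("`k` must be >= 1")
  if (k > n) stopf("`k` (%d) cannot exceed the number of points (%d)", k, n)

  centers <- if (is.null(init)) with_seed(seed, kmeanspp_init(points, k)) else {
    init <- as.matrix(init)
    if (nrow(init) != k || ncol(init) != d) stopf("`init` must be k x d")
    init
  }
  sq <- rowSums(points^2)
  assign_labels <- function(centers) {
    # n x k squared distances via the expansion |p|^2 - 2 p.c + |c|^2
    d2 <- outer(sq, rowSums(centers^2), "+") - 2 * points %*% t(centers)
    d2[d2 < 0] <- 0
    list(labels = max.col(-d2, ties.method = "first"),
         mind2 = d2[cbind(seq_len(n), max.col(-d2, ties.method = "first"))])
  }
  trace <- numeric(0)
  labels <- NULL
  for (it in seq_len(max_iter)) {
    a <- assign_labels(centers)
    labels <- a$labels
    trace <- c(trace, sum(a$mind2))
    newc <- centers
    for (j in seq_len(k)) {
      idx <- labels == j
      if (!any(idx)) {
        # empty cluster: re-seed at the point farthest from its center
        far <- which.max(a$mind2)
        newc[j, ] <- points[far, ]
      } else {
        newc[j, ] <- colMeans(points[idx, , drop = FALSE])
      }
    }
    shift <- sqrt(max(rowSums((newc - centers)^2)))
    centers <- newc
    if (shift < tol) break
  }
  a <- assign_labels(centers)
  list(labels = a$labels, centers = centers, inertia = sum(a$mind2),
       iterations = length(trace), inertia_trace = trace)
}

# k-means++ seeding (uses the current RNG stream).
kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(0, k, ncol(points))
  centers[1, ] <- points[sample.int(n, 1), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(points, 2, centers[1, ])^2)
  for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- points[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, rowSums(sweep(points, 2, centers[j, ])^2))
  }
  centers
}

#' K-means segmentation of a brain image
#'
#' Clusters pixels with [kmeans_lloyd()] (default `k = 3`: background,
#' tissue, lesion). Grayscale images are clustered on intensity; RGB
#' images on the a*, b* chromaticity coordinates of CIELAB (sRGB, D65
#' white point). The candidate tumor mask is the cluster with the highest
#' mean grayscale intensity, restricted to its largest connected
#' component. A degenerate segmentation (all pixels in one cluster, or a
#' brightest cluster indistinguishable from the rest) yields an empty
#' mask with a warning.
#'
#' @param img numeric matrix (grayscale) or `H x W x 3` array (RGB).
#' @param k number of clusters (default 3).
#' @param seed integer seed passed to [kmeans_lloyd()].
#' @return an `mri_segmentation`: list with `labels` (H x W integer map),
#'   `centers`, `inertia`, `tumor_mask` (0/1 matrix), `k`, `seed`.
#' @examples
#' ph <- make_phantom(phantom_spec(class = "benign", seed = 3))
#' seg <- segment_image(ph$image, seed = 1)
#' table(seg$labels)
#' @export
segment_image <- function(img, k = 3L, seed = 0L) {
  if (is.matrix(img)) {
    gray <- img
    feats <- matrix(as.vector(img), ncol = 1)
  } else if (length(dim(img)) == 3L && dim(img)[3] == 3L) {
    gray <- to_grayscale(img)
    rgb <- matrix(img, ncol = 3)
    lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
    feats <- lab[, 2:3, drop = FALSE]       # a*, b* only
  } else stopf("`img` must be a grayscale matrix or an H x W x 3 array")
  km <- kmeans_lloyd(feats, k = k, seed = seed)
  h <- nrow(gray); w <- ncol(gray)
  labels <- matrix(km$labels, h, w)
  mean_int <- vapply(seq_len(k), function(j) {
    v <- gray[labels == j]
    if (length(v)) mean(v) else -Inf
  }, numeric(1))
  bright <- which.max(mean_int)
  mask <- (labels == bright) * 1
  populated <- sum(is.finite(mean_int) & mean_int > -Inf)
  spread <- diff(range(mean_int[is.finite(mean_int)]))
  if (populated < 2L || spread < 1e-3) {
    warning("degenerate segmentation: no intensity structure; empty tumor mask",
            call. = FALSE)
    mask[] <- 0
  } else {
    mask <- largest_component(mask)
  }
  structure(list(labels = labels, centers = km$centers, inertia = km$inertia,
                 tumor_mask = mask, k = k, seed = seed),
            class = "mri_segmentation")
}

# Zero-based (xc, yc) centroid of the K-means tumor mask; falls back to
# the intensity centroid when segmentation finds nothing. Deterministic
# (fixed segmentation seed).
lesion_centroid <- function(img, seed = 0L) {
  seg <- suppressWarnings(segment_image(img, k = 3L, seed = seed))
  m <- seg$tumor_mask
  if (sum(m) == 0) return(intensity_centroid(img))
  xs <- colSums(m); ys <- rowSums(m)
  c(sum(xs * (seq_along(xs) - 1)) / sum(m),
    sum(ys * (seq_along(ys) - 1)) / sum(m))
}

# Keep only the largest 8-connected component of a 0/1 mask.
largest_component <- function(mask) {
  if (sum(mask) == 0) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) * 1
}

#' @export
print.mri_segmentation <- function(x, ...) {
  cat(sprintf("K-means segmentation: k = %d, inertia = %.4g, tumor mask %d px (%.1f%%)\n",
              x$k, x$inertia, sum(x$tumor_mask),
              100 * mean(x$tumor_mask)))
  invisible(x)
}
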