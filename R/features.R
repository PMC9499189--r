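# The 13-dimensional texture/intensity feature vector and the optional
# PCA / FastICA reductions. Texture features come from the gray-level
# co-occurrence matrix (GLCM): the normalized joint distribution of
# quantized intensity pairs at a fixed pixel displacement, from which the
# Haralick statistics contrast, correlation, energy, homogeneity and the
# inverse difference moment (IDM) are computed. Intensity features are
# population moments of the pixel distribution plus the Shannon entropy
# of its 256-bin histogram.

#' Names and order of the 13-dimensional feature vector
#'
#' The fixed, documented order used everywhere in the package:
#' contrast, correlation, energy, homogeneity, mean, standard_deviation,
#' entropy, rms, variance, smoothness, kurtosis, skewness, idm.
#'
#' @return character vector of length 13.
#' @export
feature_names <- function() {
  c("contrast", "correlation", "energy", "homogeneity", "mean",
    "standard_deviation", "entropy", "rms", "variance", "smoothness",
    "kurtosis", "skewness", "idm")
}

#' Gray-level co-occurrence matrix
#'
#' Quantizes intensities into `levels` equal-width bins over `[0, 1]`,
#' counts ordered pixel pairs `(p, p + offset)` where `offset = (dr, dc)`
#' is a (row, column) displacement, optionally symmetrizes (adds the
#' transpose), and normalizes the counts to sum to 1.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param levels number of quantization bins (>= 2, default 8).
#' @param offset integer `(dr, dc)` displacement, not `(0, 0)`.
#' @param symmetric if `TRUE` (default) count each pair in both orders.
#' @return a `glcm`: `levels x levels` probability matrix with attributes
#'   `levels`, `offset`, `symmetric`.
#' @export
compute_glcm <- function(img, levels = 8L, offset = c(0L, 1L),
                         symmetric = TRUE) {
  check_gray(img)
  levels <- as.integer(levels)
  if (levels < 2L) stopf("`levels` must be >= 2")
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L))
    stopf("`offset` must be a non-zero (dr, dc) pair")
  h <- nrow(img); w <- ncol(img)
  if (abs(offset[1]) >= h || abs(offset[2]) >= w)
    stopf("offset larger than the image")
  q <- matrix(pmin(floor(img * levels), levels - 1L), h, w)   # bins 0..levels-1
  r0 <- seq_len(h - abs(offset[1])) + max(0L, -offset[1])
  c0 <- seq_len(w - abs(offset[2])) + max(0L, -offset[2])
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + offset[1], c0 + offset[2], drop = FALSE]
  counts <- matrix(tabulate(a * levels + b + 1L, nbins = levels^2),
                   levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  p <- counts / sum(counts)
  structure(p, class = c("glcm", "matrix", "array"),
            levels = levels, offset = offset, symmetric = symmetric)
}

#' Haralick features of a GLCM
#'
#' With `p(i, j)` the co-occurrence probabilities over bin indices
#' `i, j = 0..L-1` and marginal means/sds `mu_i, mu_j, sigma_i, sigma_j`:
#' contrast `= sum (i-j)^2 p`; correlation
#' `= sum (i-mu_i)(j-mu_j) p / (sigma_i sigma_j)` (defined as 1 when a
#' marginal variance is zero); energy `= sum p^2`; homogeneity
#' `= sum p / (1 + |i-j|)`; inverse difference moment
#' `= sum p / (1 + (i-j)^2)`.
#'
#' @param g a `glcm` from [compute_glcm()] (any normalized square
#'   probability matrix is accepted).
#' @return named numeric vector: contrast, correlation, energy,
#'   homogeneity, idm.
#' @export
glcm_features <- function(g) {
  p <- unclass(g)
  L <- nrow(p)
  i <- matrix(0:(L - 1), L, L)        # row bin index
  j <- t(i)
  pi_ <- rowSums(p); pj <- colSums(p)
  mi <- sum((0:(L - 1)) * pi_); mj <- sum((0:(L - 1)) * pj)
  vi <- sum((0:(L - 1) - mi)^2 * pi_); vj <- sum((0:(L - 1) - mj)^2 * pj)
  corr <- if (vi <= 0 || vj <= 0) 1 else
    sum((i - mi) * (j - mj) * p) / sqrt(vi * vj)
  c(contrast = sum((i - j)^2 * p),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j))),
    idm = sum(p / (1 + (i - j)^2)))
}

#' Intensity-statistics features of a grayscale image
#'
#' Population moments over all pixels: mean, standard deviation, variance,
#' RMS (`sqrt(mean(x^2))`), smoothness (`1 - 1/(1 + variance)`), skewness
#' (standardized third moment), kurtosis (standardized fourth moment),
#' and Shannon entropy in bits of the 256-bin histogram over `[0, 1]`.
#' For a constant image the standardized moments and entropy are defined
#' as 0.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @return named numeric vector: mean, standard_deviation, entropy, rms,
#'   variance, smoothness, kurtosis, skewness.
#' @export
intensity_features <- function(img) {
  check_gray(img)
  x <- as.vector(img)
  m <- mean(x)
  v <- mean((x - m)^2)
  s <- sqrt(v)
  skew <- if (s > 0) mean((x - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - m)^4) / s^4 else 0
  bins <- pmin(floor(x * 256), 255)
  p <- tabulate(bins + 1L, nbins = 256L) / length(x)
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  c(mean = m, standard_deviation = s, entropy = ent,
    rms = sqrt(mean(x^2)), variance = v, smoothness = 1 - 1 / (1 + v),
    kurtosis = kurt, skewness = skew)
}

#' Extract the 13-dimensional feature vector from an image
#'
#' Working image: the input, optionally log-polar transformed
#' (`use_lpt`), then optionally reduced to its level-1 DWT approximation
#' sub-band LL rescaled to `[0, 1]` (`use_dwt`). The five GLCM features
#' are averaged over the four standard unit displacements (0, 45, 90,
#' 135 degrees); the eight intensity features are computed on the same
#' working image. Output order is [feature_names()].
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param use_lpt apply the log-polar transform first (default `FALSE`).
#' @param use_dwt use the level-1 DWT LL sub-band (default `TRUE`).
#' @param wavelet wavelet for the DWT step.
#' @param glcm_levels GLCM quantization bins (default 8).
#' @param lpt_M,lpt_N log-polar grid size.
#' @param lpt_center where to center the LPT: `"lesion"` (default) uses
#'   the centroid of the K-means tumor mask so the log-polar grid samples
#'   the lesion densely and tracks it under rotation and scaling of the
#'   whole image (falls back to the intensity centroid when the mask is
#'   empty); `"centroid"` uses the image intensity centroid;
#'   `"geometric"` the image center.
#' @return named numeric vector of length 13.
#' @examples
#' ph <- make_phantom(phantom_spec(class = "malignant", seed = 7))
#' extract_features(ph$image, use_lpt = TRUE)
#' @export
extract_features <- function(img, use_lpt = FALSE, use_dwt = TRUE,
                             wavelet = "haar", glcm_levels = 8L,
                             lpt_M = 64L, lpt_N = 64L,
                             lpt_center = c("lesion", "centroid",
                                            "geometric")) {
  check_gray(img)
  lpt_center <- match.arg(lpt_center)
  work <- img
  if (use_lpt) {
    ctr <- switch(lpt_center,
                  lesion = lesion_centroid(work),
                  centroid = intensity_centroid(work),
                  geometric = NULL)
    work <- unclass(lpt(work, M = lpt_M, N = lpt_N, center = ctr))
  }
  if (use_dwt) {
    ll <- dwt2(work, wavelet)$LL
    rng <- range(ll)
    work <- if (diff(rng) > 0) (ll - rng[1]) / diff(rng) else ll * 0
  }
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  gf <- rowMeans(vapply(
    offs,
    function(o) glcm_features(compute_glcm(work, levels = glcm_levels,
                                           offset = o)),
    numeric(5)))
  inten <- intensity_features(work)
  out <- c(gf[c("contrast", "correlation", "energy", "homogeneity")],
           inten[c("mean", "standard_deviation", "entropy", "rms",
                   "variance", "smoothness", "kurtosis", "skewness")],
           idm = unname(gf["idm"]))
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Fit a PCA reduction of a feature matrix
#'
#' Centers the columns and projects onto the leading eigenvectors of the
#' sample covariance (via [stats::prcomp()]). The returned model can be
#' applied to new rows with `predict()` and inverted with
#' [pca_reconstruct()].
#'
#' @param X numeric matrix, rows = observations.
#' @param n_components number of components, `1 <= n <= min(ncol, nrow-1)`.
#' @return a `pca_model`: list with `scores` (reduced matrix), `center`,
#'   `rotation`, `sdev`.
#' @export
fit_pca <- function(X, n_components) {
  X <- as.matrix(X)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(ncol(X), nrow(X) - 1L))
    stopf("`n_components` must be in [1, min(ncol, nrow - 1)]")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(scores = p$x[, seq_len(n_components), drop = FALSE],
                 center = p$center,
                 rotation = p$rotation[, seq_len(n_components), drop = FALSE],
                 sdev = p$sdev[seq_len(n_components)]),
            class = "pca_model")
}

#' @export
predict.pca_model <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2, object$center) %*% object$rotation
}

#' Reconstruct data from PCA scores
#' @param model a `pca_model`.
#' @param scores score matrix (default: the training scores).
#' @return matrix in the original feature space.
#' @export
pca_reconstruct <- function(model, scores = model$scores) {
  sweep(scores %*% t(model$rotation), 2, model$center, "+")
}

#' Fit a FastICA reduction of a feature matrix
#'
#' Whitens the centered data by PCA and runs symmetric fixed-point
#' FastICA with the `log cosh` contrast to estimate maximally
#' non-Gaussian, statistically independent components. Components are
#' identified only up to permutation, sign and scale. If every whitened
#' direction looks Gaussian (negligible excess kurtosis) the problem is
#' unidentifiable; a warning is issued and the whitened representation is
#' returned as-is.
#'
#' @param X numeric matrix, rows = observations.
#' @param n_components number of components.
#' @param seed integer seed for the random initial rotation.
#' @param max_iter,tol fixed-point iteration controls.
#' @return an `ica_model`: list with `sources` (n x k score matrix),
#'   `unmixing` (k x d, applied to centered data), `center`, `converged`.
#' @export
fit_ica <- function(X, n_components, seed = 0L, max_iter = 200L, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(d, n - 1L))
    stopf("`n_components` must be in [1, min(ncol, nrow - 1)]")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  cv <- stats::cov(Xc)
  e <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_components)
  if (any(e$values[keep] < 1e-12 * max(e$values)))
    stopf("covariance is rank-deficient for the requested components")
  K <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), n_components)   # whitening: Z = Xc K
  Z <- Xc %*% K
  k_excess <- apply(Z, 2, function(z) mean(z^4) - 3)
  if (all(abs(k_excess) < 0.2)) {
    warning("all whitened components appear Gaussian; ",
            "independent components are unidentifiable - returning the ",
            "whitened representation", call. = FALSE)
    return(structure(list(sources = Z, unmixing = t(K), center = ctr,
                          converged = FALSE, whitened_only = TRUE),
                     class = "ica_model"))
  }
  W <- with_seed(seed, {
    A <- matrix(stats::rnorm(n_components^2), n_components)
    s <- svd(A); s$u %*% t(s$v)      # random orthogonal start
  })
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)                  # n x k source estimates
    gwx <- tanh(WX)
    gp <- colMeans(1 - gwx^2)
    W1 <- t(gwx) %*% Z / n - diag(gp, n_components) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("FastICA did not converge in %d iterations; returning partial result",
                    max_iter), call. = FALSE)
  structure(list(sources = Z %*% t(W),
                 unmixing = W %*% t(K),
                 center = ctr, converged = converged, whitened_only = FALSE),
            class = "ica_model")
}

#' @export
predict.ica_model <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2, object$center) %*% t(object$unmixing)
}
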