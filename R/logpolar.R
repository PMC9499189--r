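# Log-polar transformation (LPT). Resampling an image onto a
# (log-radius, angle) grid about a center turns rotations about that
# center into circular shifts along the angle axis and uniform scalings
# into translations along the log-radius axis, which is what makes
# downstream texture features tolerant to rotated and rescaled inputs.
#
# Conventions (fixed so shift signs are testable): coordinates are
# zero-based with x along columns and y along rows (y grows downward);
# theta = atan2(y - yc, x - xc) wrapped to [0, 2*pi); the log is natural.

#' Cartesian to log-polar coordinates
#'
#' Maps a point to `(rho, theta)` where `rho = log` of the Euclidean
#' distance from the center and `theta = atan2(y - yc, x - xc)` wrapped to
#' `[0, 2*pi)`.
#'
#' @param x,y numeric vectors of point coordinates.
#' @param center numeric length-2 vector `(xc, yc)`.
#' @return list with components `rho` and `theta`.
#' @export
cart_to_logpolar <- function(x, y, center = c(0, 0)) {
  dx <- x - center[1]; dy <- y - center[2]
  r2 <- dx^2 + dy^2
  if (any(r2 == 0)) stopf("point coincides with the center: log-radius undefined")
  theta <- atan2(dy, dx) %% (2 * pi)
  list(rho = 0.5 * log(r2), theta = theta)
}

#' Log-polar to Cartesian coordinates
#'
#' Inverse of [cart_to_logpolar()] (up to the center offset):
#' `x = exp(rho) * cos(theta)`, `y = exp(rho) * sin(theta)`.
#'
#' @param rho,theta numeric vectors.
#' @return list with components `x` and `y`.
#' @export
logpolar_to_cart <- function(rho, theta) {
  r <- exp(rho)
  list(x = r * cos(theta), y = r * sin(theta))
}

#' Log-polar transform of a grayscale image
#'
#' Resamples `img` onto an `M x N` grid: rows are `M` log-radius samples
#' uniformly covering `[log(r_min), log(r_max)]`, columns are `N` angle
#' samples uniformly covering `[0, 2*pi)`. Sampling uses bilinear
#' interpolation; samples falling outside the image take the fill value.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param M,N output rows (log-radius) and columns (angle); both >= 2.
#' @param r_min inner radius in pixels (>= 0.5).
#' @param r_max outer radius in pixels, or `NULL` for `min(H, W) / 2`.
#' @param center `(xc, yc)` in zero-based pixel coordinates, or `NULL` for
#'   the geometric center `((W - 1) / 2, (H - 1) / 2)`.
#' @param fill out-of-field fill: a number (default 0) or `"nearest"`.
#' @return a `logpolar_image`: the `M x N` pixel matrix with attributes
#'   `center`, `r_min`, `r_max` and `source_dim`.
#' @examples
#' ph <- make_phantom(phantom_spec(class = "benign", seed = 1))
#' lp <- lpt(ph$image, M = 64, N = 64)
#' dim(lp)
#' @export
lpt <- function(img, M = 64L, N = 64L, r_min = 1, r_max = NULL,
                center = NULL, fill = 0) {
  check_gray(img)
  M <- as.integer(M); N <- as.integer(N)
  if (M < 2L || N < 2L) stopf("M and N must be >= 2")
  if (r_min < 0.5) stopf("r_min must be >= 0.5 pixel")
  h <- nrow(img); w <- ncol(img)
  if (is.null(r_max)) r_max <- min(h, w) / 2
  if (r_min >= r_max) stopf("r_min must be < r_max")
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  rho <- seq(log(r_min), log(r_max), length.out = M)
  theta <- 2 * pi * (seq_len(N) - 1L) / N
  r <- exp(rho)
  xs <- center[1] + outer(r, cos(theta))          # M x N
  ys <- center[2] + outer(r, sin(theta))
  px <- matrix(bilinear_sample(img, as.vector(xs), as.vector(ys), fill = fill),
               M, N)
  structure(px, class = c("logpolar_image", "matrix", "array"),
            center = center, r_min = r_min, r_max = r_max,
            source_dim = c(h, w))
}

#' @export
print.logpolar_image <- function(x, ...) {
  cat(sprintf(
    "log-polar image: %d rho x %d theta, r in [%.3g, %.3g], center (%.2f, %.2f), source %dx%d\n",
    nrow(x), ncol(x), attr(x, "r_min"), attr(x, "r_max"),
    attr(x, "center")[1], attr(x, "center")[2],
    attr(x, "source_dim")[1], attr(x, "source_dim")[2]))
  invisible(x)
}

#' Circularly shift the angle columns of a log-polar image
#'
#' Shifts columns right by `k` positions (mod `N`), preserving metadata.
#' A rotation of the source image by `delta` degrees corresponds to a
#' column shift of `round(N * delta / 360)`.
#'
#' @param lp a `logpolar_image`.
#' @param k integer shift.
#' @return shifted `logpolar_image`.
#' @export
column_shift <- function(lp, k) {
  n <- ncol(lp)
  k <- as.integer(k) %% n
  if (k != 0L) {
    at <- attributes(lp)
    lp <- lp[, c((n - k + 1L):n, seq_len(n - k)), drop = FALSE]
    attributes(lp) <- at
  }
  lp
}

#' Rotate a grayscale image about its center
#'
#' Bilinear resampling with zero fill; angles follow the same convention
#' as [lpt()], so `rotate_image(img, delta)` shifts `lpt(img)` columns by
#' `round(N * delta / 360)`. The output has the input's shape.
#'
#' @param img numeric matrix.
#' @param angle_deg rotation angle in degrees.
#' @param fill out-of-field fill value (default 0) or `"nearest"`.
#' @return rotated matrix.
#' @export
rotate_image <- function(img, angle_deg, fill = 0) {
  check_gray(img)
  h <- nrow(img); w <- ncol(img)
  xc <- (w - 1) / 2; yc <- (h - 1) / 2
  a <- angle_deg * pi / 180
  # a point at angle theta in the source appears at theta + a in the
  # output; sample the source at the back-rotated position
  cx <- rep(seq_len(w) - 1, each = h) - xc
  cy <- rep(seq_len(h) - 1, times = w) - yc
  sx <- cos(a) * cx + sin(a) * cy + xc
  sy <- -sin(a) * cx + cos(a) * cy + yc
  matrix(bilinear_sample(img, sx, sy, fill = fill), h, w)
}

#' Translation sensitivity of the log-polar transform
#'
#' The LPT is invariant to rotation and scaling about its center but not
#' to translation: shifting the image content while keeping the center
#' fixed changes every log-polar sample. This helper quantifies that
#' sensitivity as the mean absolute difference between the LPT of the
#' translated image (center unchanged) and the LPT of the original.
#'
#' @param img numeric matrix.
#' @param dx,dy translation in pixels; must satisfy
#'   `abs(dx), abs(dy) < min(H, W) / 4`.
#' @param M,N log-polar grid size.
#' @param ... further arguments passed to [lpt()].
#' @return non-negative scalar; 0 when `dx = dy = 0`.
#' @export
translate_sensitivity <- function(img, dx, dy, M = 64L, N = 64L, ...) {
  check_gray(img)
  lim <- min(dim(img)) / 4
  if (abs(dx) >= lim || abs(dy) >= lim)
    stopf("|dx| and |dy| must be < min(H, W) / 4 = %.1f", lim)
  shifted <- translate_image(img, dx, dy)
  mean(abs(lpt(shifted, M, N, ...) - lpt(img, M, N, ...)))
}

# Translate image content by (dx, dy) pixels (bilinear, zero fill).
translate_image <- function(img, dx, dy, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  sx <- rep(seq_len(w) - 1, each = h) - dx
  sy <- rep(seq_len(h) - 1, times = w) - dy
  matrix(bilinear_sample(img, sx, sy, fill = fill), h, w)
}

# Intensity centroid of an image, zero-based (xc, yc); used to re-center
# off-center content before the LPT.
intensity_centroid <- function(img) {
  tot <- sum(img)
  if (tot <= 0) return(c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2))
  xs <- colSums(img) %*% (seq_len(ncol(img)) - 1) / tot
  ys <- rowSums(img) %*% (seq_len(nrow(img)) - 1) / tot
  c(as.numeric(xs), as.numeric(ys))
}
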