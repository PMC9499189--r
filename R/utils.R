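# Internal helpers shared across modules.

#' @useDynLib lptbrain, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# the global stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a per-item seed from a master seed; stays inside 32-bit range.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + as.numeric(i) * 104729) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_gray_image <- function(img) is.matrix(img) && is.numeric(img)

check_gray <- function(img, arg = "img") {
  if (!is_gray_image(img))
    stopf("`%s` must be a numeric matrix (grayscale image)", arg)
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Bilinear sampling of a grayscale image at arbitrary coordinates
#'
#' Samples `img` at continuous positions using bilinear interpolation.
#' Coordinates are zero-based: `x` runs along columns, `y` along rows, so
#' pixel `img[r, c]` sits at `(x, y) = (c - 1, r - 1)`. Samples falling
#' outside the image evaluate to `fill` (the default) or to the nearest
#' border pixel when `fill = "nearest"`.
#'
#' @param img numeric matrix (grayscale image).
#' @param x,y numeric vectors of equal length, zero-based sample positions.
#' @param fill either a numeric fill value for out-of-field samples or the
#'   string `"nearest"` to clamp to the border.
#' @return numeric vector of sampled intensities, same length as `x`.
#' @keywords internal
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  nearest <- identical(fill, "nearest")
  if (nearest) {
    x <- pmin(pmax(x, 0), w - 1)
    y <- pmin(pmax(y, 0), h - 1)
  }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp the four corner indices; weights keep the true position
  gx0 <- pmin(pmax(x0, 0), w - 1); gx1 <- pmin(pmax(x0 + 1, 0), w - 1)
  gy0 <- pmin(pmax(y0, 0), h - 1); gy1 <- pmin(pmax(y0 + 1, 0), h - 1)
  v00 <- img[cbind(gy0 + 1, gx0 + 1)]
  v01 <- img[cbind(gy0 + 1, gx1 + 1)]
  v10 <- img[cbind(gy1 + 1, gx0 + 1)]
  v11 <- img[cbind(gy1 + 1, gx1 + 1)]
  out <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
    fy * ((1 - fx) * v10 + fx * v11)
  if (!nearest) {
    # a hair of slack so grid-exact samples (e.g. pure half-turns) do not
    # fall out of field through floating-point jitter
    eps <- 1e-9
    outside <- x < -eps | x > (w - 1) + eps | y < -eps | y > (h - 1) + eps
    if (any(outside)) out[outside] <- fill
  }
  out
}
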