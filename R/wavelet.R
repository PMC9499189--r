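# Separable 2-D discrete wavelet transform. One level splits an image
# into the approximation sub-band LL and the detail sub-bands LH, HL, HH
# by low/high-pass filtering rows then columns with stride-2 decimation;
# a multi-level decomposition reuses each LL as the input of the next
# level. Filters are orthonormal (Haar, db4) and the boundary is handled
# by periodization, so the one-level transform is an orthogonal linear
# map: energy is conserved exactly and the inverse transform gives
# perfect reconstruction. Odd-length inputs are padded by replicating the
# last sample, giving ceil(n/2)-length sub-bands.

# Orthonormal analysis low-pass filters. High-pass is the quadrature
# mirror g[m] = (-1)^m h[L - 1 - m].
wavelet_filters <- function(wavelet = c("haar", "db4")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db4 = c(0.23037781330889651, 0.71484657055291567,
            0.63088076792985892, -0.027983769416859854,
            -0.18703481171909309, 0.030841381835560764,
            0.032883011666885197, -0.010597401785069032))
  m <- seq_along(h) - 1
  list(h = h, g = (-1)^m * rev(h))
}

# n x n orthogonal one-level DWT matrix for even n >= filter length:
# rows 1..n/2 are even shifts of the periodized low-pass filter, rows
# n/2+1..n of the high-pass filter.
dwt_matrix <- function(n, wavelet) {
  f <- wavelet_filters(wavelet)
  L <- length(f$h)
  if (n %% 2L != 0L) stopf("internal: dwt_matrix needs even n")
  W <- matrix(0, n, n)
  half <- n / 2L
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L)) + seq_len(L) - 1L) %% n + 1L
    for (m in seq_len(L)) {
      W[k, idx[m]] <- W[k, idx[m]] + f$h[m]
      W[half + k, idx[m]] <- W[half + k, idx[m]] + f$g[m]
    }
  }
  W
}

# Pad odd dimensions by replicating the final row/column.
pad_even <- function(img) {
  if (nrow(img) %% 2L == 1L) img <- rbind(img, img[nrow(img), ])
  if (ncol(img) %% 2L == 1L) img <- cbind(img, img[, ncol(img)])
  img
}

#' Single-level 2-D discrete wavelet transform
#'
#' Decomposes a grayscale image into the four sub-bands LL, LH, HL, HH by
#' filtering columns then rows with the orthonormal analysis pair and
#' decimating by 2 (periodized boundary). Sub-bands have dimensions
#' `ceiling(H/2) x ceiling(W/2)`. In the sub-band names the first letter
#' refers to the row direction and the second to the column direction; LH
#' carries horizontal detail (edges along rows), HL vertical detail.
#'
#' @param img numeric matrix with `H, W >= 2`.
#' @param wavelet `"haar"` (default) or `"db4"`.
#' @return list with matrices `LL`, `LH`, `HL`, `HH`.
#' @examples
#' b <- dwt2(matrix(1, 2, 2))
#' b$LL   # 2 for a constant image of ones
#' @export
dwt2 <- function(img, wavelet = "haar") {
  check_gray(img)
  if (nrow(img) < 2L || ncol(img) < 2L) stopf("image must be at least 2 x 2")
  img <- pad_even(img)
  Wr <- dwt_matrix(nrow(img), wavelet)
  Wc <- dwt_matrix(ncol(img), wavelet)
  y <- Wr %*% img %*% t(Wc)   # rows: low block then high block, same for cols
  hr <- nrow(img) / 2L; hc <- ncol(img) / 2L
  list(LL = y[seq_len(hr), seq_len(hc), drop = FALSE],
       LH = y[seq_len(hr), hc + seq_len(hc), drop = FALSE],
       HL = y[hr + seq_len(hr), seq_len(hc), drop = FALSE],
       HH = y[hr + seq_len(hr), hc + seq_len(hc), drop = FALSE])
}

#' Inverse single-level 2-D discrete wavelet transform
#'
#' Synthesis filter bank; exact inverse of [dwt2()] for even input
#' dimensions (the transform matrix is orthogonal).
#'
#' @param LL,LH,HL,HH sub-band matrices of identical dimensions.
#' @param wavelet `"haar"` (default) or `"db4"`.
#' @return reconstructed matrix of dimension `2*nrow(LL) x 2*ncol(LL)`.
#' @export
idwt2 <- function(LL, LH, HL, HH, wavelet = "haar") {
  d <- dim(LL)
  if (!identical(d, dim(LH)) || !identical(d, dim(HL)) || !identical(d, dim(HH)))
    stopf("sub-band shapes differ")
  y <- rbind(cbind(LL, LH), cbind(HL, HH))
  Wr <- dwt_matrix(2L * d[1], wavelet)
  Wc <- dwt_matrix(2L * d[2], wavelet)
  t(Wr) %*% y %*% Wc
}

#' Multi-level 2-D wavelet decomposition
#'
#' Cascades [dwt2()], re-applying it to each successive LL sub-band.
#'
#' @param img numeric matrix.
#' @param levels number of decomposition levels (>= 1).
#' @param wavelet `"haar"` (default) or `"db4"`.
#' @return a `wavelet_decomposition`: list with `levels` (each a list of
#'   `LL`, `LH`, `HL`, `HH`), `wavelet` and `boundary` (`"periodization"`).
#' @export
wavedec2 <- function(img, levels = 1L, wavelet = "haar") {
  check_gray(img)
  levels <- as.integer(levels)
  if (levels < 1L) stopf("`levels` must be >= 1")
  L <- length(wavelet_filters(wavelet)$h)
  out <- vector("list", levels)
  cur <- img
  for (j in seq_len(levels)) {
    if (min(dim(cur)) < max(2L, L))
      stopf("decomposition level %d infeasible for image of size %dx%d",
            j, nrow(img), ncol(img))
    b <- dwt2(cur, wavelet)
    out[[j]] <- b
    cur <- b$LL
  }
  structure(list(levels = out, wavelet = wavelet, boundary = "periodization"),
            class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("%d-level 2-D DWT (%s, %s boundary)\n",
              length(x$levels), x$wavelet, x$boundary))
  for (j in seq_along(x$levels))
    cat(sprintf("  level %d: 4 sub-bands of %d x %d\n", j,
                nrow(x$levels[[j]]$LL), ncol(x$levels[[j]]$LL)))
  invisible(x)
}
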