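# Shared fixtures and independent oracles, built in code.

dice_coef <- function(a, b) 2 * sum(a * b) / (sum(a) + sum(b))

# Image whose intensity depends on radius only (concentric rings).
ring_image <- function(h = 256, w = 256, period = 6) {
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  r <- sqrt((x - (w - 1) / 2)^2 + (y - (h - 1) / 2)^2)
  0.5 + 0.4 * cos(r / period)
}

# Brute-force GLCM feature oracle: explicit double loop over all bin
# pairs, written independently of the package's vectorized code.
glcm_features_oracle <- function(p) {
  L <- nrow(p)
  contrast <- energy <- homog <- idm <- 0
  mi <- mj <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    mi <- mi + i * p[i + 1, j + 1]
    mj <- mj + j * p[i + 1, j + 1]
  }
  vi <- vj <- covv <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    pij <- p[i + 1, j + 1]
    contrast <- contrast + (i - j)^2 * pij
    energy <- energy + pij^2
    homog <- homog + pij / (1 + abs(i - j))
    idm <- idm + pij / (1 + (i - j)^2)
    vi <- vi + (i - mi)^2 * pij
    vj <- vj + (j - mj)^2 * pij
    covv <- covv + (i - mi) * (j - mj) * pij
  }
  corr <- if (vi <= 0 || vj <= 0) 1 else covv / sqrt(vi * vj)
  c(contrast = contrast, correlation = corr, energy = energy,
    homogeneity = homog, idm = idm)
}

# Exhaustive k-means oracle: minimum within-cluster sum of squares over
# every assignment of n points to k clusters (feasible for n <= 8).
kmeans_oracle <- function(points, k) {
  n <- length(points)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf; best_assign <- NULL
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (length(unique(a)) < k) next
    sse <- sum(vapply(seq_len(k), function(j) {
      v <- points[a == j]
      sum((v - mean(v))^2)
    }, numeric(1)))
    if (sse < best) { best <- sse; best_assign <- a }
  }
  centers <- vapply(seq_len(k), function(j) mean(points[best_assign == j]),
                    numeric(1))
  list(inertia = best, centers = sort(centers))
}

# Chain-code perimeter with the Kulpa straight/diagonal correction.
mask_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask))[[1]]
  d <- sqrt(rowSums((oc - oc[c(2:nrow(oc), 1), ])^2))
  0.9481 * sum(d)
}
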