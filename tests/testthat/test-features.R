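test_that("GLCM counts pairs correctly on hand-checked images", {
  # two rows: 0s above 1s; the two horizontal pairs are (0,0) and (1,1)
  img <- rbind(c(0, 0), c(1, 1))
  g <- compute_glcm(img, levels = 2, offset = c(0, 1), symmetric = FALSE)
  expect_equal(unclass(g), matrix(c(0.5, 0, 0, 0.5), 2, 2),
               ignore_attr = TRUE)
  gc <- compute_glcm(matrix(0.42, 6, 6), levels = 8)
  expect_equal(sum(gc), 1)
  expect_equal(max(gc), 1)   # all mass in one diagonal cell
  set.seed(1)
  r <- matrix(runif(64), 8, 8)
  gs <- compute_glcm(r, levels = 4, offset = c(-1, 1), symmetric = TRUE)
  expect_equal(unclass(gs), t(unclass(gs)), ignore_attr = TRUE)
  expect_error(compute_glcm(r, offset = c(0, 0)), "offset")
})

test_that("Haralick features match hand calculations on degenerate GLCMs", {
  fc <- glcm_features(compute_glcm(matrix(0.9, 5, 5)))
  expect_equal(unname(fc), c(0, 1, 1, 1, 1))
  g2 <- compute_glcm(rbind(c(0, 0), c(1, 1)), levels = 2,
                     offset = c(0, 1), symmetric = FALSE)
  f2 <- glcm_features(g2)
  expect_equal(unname(f2["contrast"]), 0)
  expect_equal(unname(f2["energy"]), 0.5)
  expect_equal(unname(f2["homogeneity"]), 1)
  expect_equal(unname(f2["idm"]), 1)
})

test_that("all five GLCM features equal the brute-force oracle", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    img <- matrix(runif(64), 8, 8)
    g <- compute_glcm(img, levels = 8,
                      offset = sample(list(c(0L, 1L), c(-1L, 1L),
                                           c(-1L, 0L), c(-1L, -1L)), 1)[[1]],
                      symmetric = sample(c(TRUE, FALSE), 1))
    worst <- max(worst, abs(glcm_features(g) - glcm_features_oracle(unclass(g))))
  }
  expect_lt(worst, 1e-12)
})

test_that("intensity features match two-point and constant distributions", {
  fc <- intensity_features(matrix(0.6, 4, 4))
  expect_equal(unname(fc[c("mean", "standard_deviation", "variance",
                           "smoothness", "entropy", "skewness",
                           "kurtosis")]),
               c(0.6, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(fc["rms"]), 0.6)
  half <- cbind(matrix(0, 4, 2), matrix(1 - 1e-9, 4, 2))
  fh <- intensity_features(half)
  expect_equal(unname(fh["mean"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(fh["variance"]), 0.25, tolerance = 1e-8)
  expect_equal(unname(fh["rms"]), sqrt(0.5), tolerance = 1e-8)
  expect_equal(unname(fh["entropy"]), 1, tolerance = 1e-8)
  expect_equal(unname(fh["skewness"]), 0, tolerance = 1e-7)
  set.seed(5)
  for (i in 1:20) {
    f <- intensity_features(matrix(runif(100), 10, 10))
    expect_lt(abs(f["rms"]^2 - f["variance"] - f["mean"]^2), 1e-12)
  }
})

test_that("extract_features always yields the 13 named features, deterministically", {
  ph <- make_phantom(phantom_spec(class = "malignant", seed = 3))
  for (lptf in c(FALSE, TRUE)) for (dwtf in c(FALSE, TRUE)) {
    fv <- extract_features(ph$image, use_lpt = lptf, use_dwt = dwtf)
    expect_length(fv, 13L)
    expect_identical(names(fv), feature_names())
    expect_true(all(is.finite(fv)))
  }
  expect_identical(extract_features(ph$image, use_lpt = TRUE),
                   extract_features(ph$image, use_lpt = TRUE))
})

test_that("log-polar features move less under rotation than raw features", {
  set.seed(6)
  wins <- 0
  for (s in 1:10) {
    ph <- make_phantom(phantom_spec(
      class = sample(c("benign", "malignant"), 1), seed = s))
    f0l <- extract_features(ph$image, use_lpt = TRUE)
    f0n <- extract_features(ph$image, use_lpt = FALSE)
    d <- rowMeans(vapply(c(45, 90, 135), function(a) {
      r <- rotate_image(ph$image, a)
      c(lpt = sqrt(sum((extract_features(r, use_lpt = TRUE) - f0l)^2)),
        raw = sqrt(sum((extract_features(r, use_lpt = FALSE) - f0n)^2)))
    }, numeric(2)))
    wins <- wins + (d["lpt"] < d["raw"])
  }
  expect_gt(wins / 10, 0.5)
})

test_that("PCA reduces, orders variance, reconstructs at full rank", {
  set.seed(7)
  X <- matrix(rnorm(40 * 13), 40, 13) %*% diag(seq(2, 0.5, length.out = 13))
  p <- fit_pca(X, 13)
  expect_true(all(diff(p$sdev) <= 1e-12))
  expect_lt(max(abs(pca_reconstruct(p) - X)), 1e-9)
  expect_equal(predict(p, X), p$scores)
  expect_error(fit_pca(X, 14), "n_components")
  # known principal axis of a correlated 2-D Gaussian
  S <- matrix(c(2, 1.2, 1.2, 1), 2, 2)
  L <- chol(S)
  Y <- matrix(rnorm(1000), 500, 2) %*% L
  axis_hat <- fit_pca(Y, 1)$rotation[, 1]
  axis_true <- eigen(stats::cov(Y))$vectors[, 1]
  ang <- acos(min(1, abs(sum(axis_hat * axis_true)))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("FastICA recovers independent uniform sources up to sign and order", {
  set.seed(8)
  S <- cbind(runif(2000, -1, 1), runif(2000, -1, 1))
  A <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  X <- S %*% t(A)
  ic <- fit_ica(X, 2, seed = 1)
  expect_true(ic$converged)
  cors <- abs(stats::cor(ic$sources, S))
  # each true source strongly matches exactly one recovered component
  expect_gt(min(apply(cors, 2, max)), 0.95)
  ic2 <- fit_ica(X, 2, seed = 1)
  expect_identical(ic$sources, ic2$sources)
})

test_that("Gaussian-only input is flagged unidentifiable but still whitened", {
  set.seed(9)
  X <- matrix(rnorm(3000), 1000, 3)
  expect_warning(ic <- fit_ica(X, 2, seed = 1), "Gaussian")
  expect_true(ic$whitened_only)
  cv <- stats::cov(ic$sources)
  expect_lt(max(abs(cv - diag(2))), 0.1)
})
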