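test_that("coordinate maps follow the atan2 convention and invert exactly", {
  cp <- cart_to_logpolar(3, 4, c(0, 0))
  expect_equal(cp$rho, log(5))
  expect_equal(cp$theta, atan2(4, 3))
  cp2 <- cart_to_logpolar(1, 0, c(0, 0))
  expect_equal(cp2$rho, 0); expect_equal(cp2$theta, 0)
  expect_equal(cart_to_logpolar(0, -1, c(0, 0))$theta, 3 * pi / 2)
  expect_error(cart_to_logpolar(2, 3, c(2, 3)), "center")
  xy <- logpolar_to_cart(0, 0)
  expect_equal(c(xy$x, xy$y), c(1, 0))
  xy2 <- logpolar_to_cart(log(2), pi / 2)
  expect_equal(c(xy2$x, xy2$y), c(0, 2), tolerance = 1e-12)
  set.seed(1)
  x <- runif(100, -50, 50); y <- runif(100, -50, 50)
  keep <- abs(x) + abs(y) > 1e-3
  cp <- cart_to_logpolar(x[keep], y[keep])
  back <- logpolar_to_cart(cp$rho, cp$theta)
  expect_lt(max(abs(back$x - x[keep]), abs(back$y - y[keep])), 1e-9)
})

test_that("lpt of a constant image is constant away from the fill boundary", {
  lp <- lpt(matrix(0.7, 64, 64), M = 32, N = 32, r_min = 1, r_max = 30)
  expect_equal(unclass(lp), matrix(0.7, 32, 32), ignore_attr = TRUE)
  expect_error(lpt(matrix(0.5, 32, 32), r_min = 10, r_max = 5), "r_min")
})

test_that("lpt rows are constant in angle for a radially symmetric image", {
  ring <- ring_image(128, 128)
  lp <- lpt(ring, M = 48, N = 64, r_min = 1, r_max = 60)
  row_spread <- apply(lp, 1, function(r) max(r) - min(r))
  expect_lt(max(row_spread[2:47]), 1e-2)
  # structure is there: values vary along rho
  expect_gt(max(lp) - min(lp), 0.5)
})

test_that("rotation of the source becomes a circular column shift", {
  ph <- make_phantom(phantom_spec(class = "benign", seed = 2,
                                  noise_sigma = 0))
  for (d in c(30, 90, 137)) {
    l_rot <- lpt(rotate_image(ph$image, d), M = 64, N = 64)
    l_shift <- column_shift(lpt(ph$image, M = 64, N = 64),
                            round(64 * d / 360))
    expect_lt(mean(abs(l_rot - l_shift)), 0.02)
  }
})

test_that("uniform scaling becomes a row shift of log(alpha)/drho bins", {
  ring <- ring_image(256, 256)
  M <- 64; r_min <- 1; r_max <- 128
  drho <- (log(r_max) - log(r_min)) / (M - 1)
  l0 <- lpt(ring, M, 64, r_min, r_max)
  for (alpha in c(0.5, 1.5)) {
    l1 <- lpt(distort(ring, 0, alpha), M, 64, r_min, r_max)
    shifts <- -20:20
    cost <- vapply(shifts, function(s) {
      rows0 <- 21:(M - 21); rows1 <- rows0 + s
      ok <- rows1 >= 1 & rows1 <= M
      mean(abs(l0[rows0[ok], ] - l1[rows1[ok], ]))
    }, numeric(1))
    est <- shifts[which.min(cost)]
    expect_lt(abs(est - log(alpha) / drho), 1)
  }
})

test_that("column_shift composes to the identity and keeps metadata", {
  lp <- lpt(ring_image(64, 64), M = 16, N = 20)
  expect_equal(column_shift(lp, 0), lp)
  expect_equal(column_shift(lp, 20), lp)
  expect_equal(column_shift(column_shift(lp, 7), 13), lp)
  expect_equal(attr(column_shift(lp, 3), "r_min"), attr(lp, "r_min"))
})

test_that("lpt is deterministic and bounded by the input range", {
  ph <- make_phantom(phantom_spec(class = "malignant", seed = 4))
  a <- lpt(ph$image); b <- lpt(ph$image)
  expect_identical(unclass(a), unclass(b))
  expect_gte(min(a), 0)
  expect_lte(max(a), max(ph$image) + 1e-12)
})

test_that("translation sensitivity is zero at rest, grows, and vanishes on re-centering", {
  ph <- make_phantom(phantom_spec(class = "benign", seed = 0,
                                  noise_sigma = 0))
  img <- ph$image
  expect_identical(translate_sensitivity(img, 0, 0), 0)
  sens <- vapply(c(0, 1, 2, 4), function(dx)
    translate_sensitivity(img, dx, 0), numeric(1))
  expect_true(all(diff(sens) > 0))
  # re-centering on the centroid restores near-invariance
  shifted <- lptbrain:::translate_image(img, 5, 3)
  lp0 <- lpt(img, center = lptbrain:::intensity_centroid(img))
  lp1 <- lpt(shifted, center = lptbrain:::intensity_centroid(shifted))
  expect_lt(mean(abs(lp1 - lp0)), 0.01)
  expect_error(translate_sensitivity(img, 100, 0), "dx")
})
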