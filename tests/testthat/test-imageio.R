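test_that("load_image normalizes and promotes all three formats", {
  d <- withr::local_tempdir()
  white <- matrix(1, 2, 2)
  black <- matrix(0, 2, 2)
  f_png <- file.path(d, "w.png"); save_image(white, f_png)
  expect_equal(load_image(f_png), array(1, c(2, 2, 3)))
  f_bmp <- file.path(d, "b.bmp"); save_image(black, f_bmp)
  expect_equal(load_image(f_bmp), array(0, c(2, 2, 3)))
  expect_error(load_image(file.path(d, "missing.png")), "not found")
  f_bad <- file.path(d, "x.gif"); file.create(f_bad)
  expect_error(load_image(f_bad), "unsupported")
})

test_that("png and bmp round-trip within 8-bit quantization", {
  d <- withr::local_tempdir()
  set.seed(1)
  img <- matrix(runif(20 * 17), 20, 17)
  for (ext in c("png", "bmp")) {
    f <- file.path(d, paste0("rt.", ext))
    save_image(img, f)
    back <- to_grayscale(load_image(f))
    expect_lt(max(abs(back - img)), 1 / 255 + 1e-12)
  }
  # color bmp keeps channels in order
  rgb <- array(runif(6 * 5 * 3), c(6, 5, 3))
  f <- file.path(d, "c.bmp"); save_image(rgb, f)
  expect_lt(max(abs(load_image(f) - rgb)), 1 / 255 + 1e-12)
})

test_that("to_grayscale applies BT.601 luminance weights", {
  gray_half <- array(0.5, c(3, 3, 3))
  expect_equal(to_grayscale(gray_half), matrix(0.5, 3, 3))
  red <- array(0, c(2, 2, 3)); red[, , 1] <- 1
  expect_equal(to_grayscale(red), matrix(0.299, 2, 2))
  # promoted grayscale equals its channel
  g <- matrix(runif(9), 3, 3)
  promoted <- array(rep(g, 3), c(3, 3, 3))
  expect_equal(to_grayscale(promoted), g)
  # bounded by channel min/max at each pixel
  set.seed(2)
  rgb <- array(runif(4 * 4 * 3), c(4, 4, 3))
  lum <- to_grayscale(rgb)
  expect_true(all(lum >= apply(rgb, c(1, 2), min) - 1e-12))
  expect_true(all(lum <= apply(rgb, c(1, 2), max) + 1e-12))
})

test_that("binarize thresholds correctly and Otsu splits a bimodal image", {
  expect_equal(binarize(matrix(0.8, 3, 3), 0.5), matrix(1, 3, 3))
  expect_equal(binarize(matrix(0.2, 3, 3), 0.5), matrix(0, 3, 3))
  expect_error(binarize(matrix(0.5, 2, 2), 1.5), "threshold")
  set.seed(3)
  img <- matrix(sample(c(0.1, 0.9), 400, replace = TRUE), 20, 20)
  expect_equal(binarize(img, "otsu"), (img == 0.9) * 1)
  # idempotent on its own output
  bin <- binarize(img, "otsu")
  expect_equal(binarize(bin, 0.5), bin)
})

test_that("median denoising removes a hot pixel and keeps constants", {
  img <- matrix(0.4, 5, 5)
  expect_equal(denoise(img, 3), img)
  expect_identical(denoise(img, 1), img)
  hot <- matrix(0, 7, 7); hot[4, 4] <- 1
  expect_equal(denoise(hot, 3)[4, 4], 0)
  expect_error(denoise(img, 4), "odd")
})

test_that("bilinear resize is exact on identity and constants, monotone on ramps", {
  set.seed(4)
  img <- matrix(runif(30), 5, 6)
  expect_equal(resize_image(img, 5, 6), img)
  expect_equal(resize_image(matrix(0.3, 4, 4), 9, 7), matrix(0.3, 9, 7))
  ramp <- matrix(c(0, 0, 1, 1), 2, 2)
  up <- resize_image(ramp, 2, 4)
  expect_true(all(diff(t(up)) >= 0))
  expect_error(resize_image(img, 0, 5), "positive")
  # down-up round trip on a smooth image
  smooth <- ring_image(40, 40, period = 10)
  rt <- resize_image(resize_image(smooth, 80, 80), 40, 40)
  expect_lt(mean(abs(rt - smooth)), 0.05)
})
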