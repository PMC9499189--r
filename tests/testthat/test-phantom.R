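test_that("phantom specs enforce the class conventions", {
  expect_error(phantom_spec(class = "benign", irregularity = 0.4),
               "benign")
  expect_error(phantom_spec(class = "malignant", irregularity = 0.1,
                            heterogeneity = 0.1), "malignant")
  sp <- phantom_spec(class = "normal", seed = 1)
  expect_equal(sp$irregularity, 0)
})

test_that("phantoms are deterministic, bounded, and normals have no lesion", {
  ph_n <- make_phantom(phantom_spec(class = "normal", seed = 4))
  expect_equal(sum(ph_n$mask), 0)
  a <- make_phantom(phantom_spec(class = "malignant", seed = 9))
  b <- make_phantom(phantom_spec(class = "malignant", seed = 9))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_gte(min(a$image), 0); expect_lte(max(a$image), 1)
  expect_gt(sum(a$mask), 0)
  expect_error(make_phantom(phantom_spec(
    class = "benign", lesion_center = c(5, 5), seed = 1)), "ellipse")
})

test_that("a zero-irregularity lesion rasterizes as a disk", {
  ph <- make_phantom(phantom_spec(class = "benign", irregularity = 0,
                                  heterogeneity = 0, seed = 2))
  per <- mask_perimeter(ph$mask)
  ratio <- per^2 / (4 * pi * sum(ph$mask))
  expect_lt(ratio, 1.1)
})

test_that("malignant texture separates from benign at matched seeds", {
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  glcm_avg <- function(img) {
    rowMeans(vapply(offs, function(o)
      glcm_features(compute_glcm(img, offset = o)), numeric(5)))
  }
  res <- vapply(1:30, function(s) {
    fb <- glcm_avg(make_phantom(phantom_spec(class = "benign", seed = s))$image)
    fm <- glcm_avg(make_phantom(phantom_spec(class = "malignant", seed = s))$image)
    c(dc = unname(fm["contrast"] - fb["contrast"]),
      dh = unname(fm["homogeneity"] - fb["homogeneity"]))
  }, numeric(2))
  # contrast separates in every matched pair; homogeneity in the mean
  # and in at least 90% of pairs (near-ties can occur at low
  # heterogeneity draws)
  expect_true(all(res["dc", ] > 0))
  expect_lt(mean(res["dh", ]), 0)
  expect_gte(mean(res["dh", ] < 0), 0.9)
})

test_that("distort handles identity, range checks, and exact 90-degree turns", {
  ph <- make_phantom(phantom_spec(class = "benign", seed = 5))
  expect_equal(distort(ph$image, 0, 1), ph$image)
  expect_error(distort(ph$image, 360, 1), "angle")
  expect_error(distort(ph$image, 0, 2), "scale")
  # half turns from either side agree
  expect_lt(max(abs(distort(ph$image, 180, 1) - distort(ph$image, -180, 1))),
            1e-6)
  # an odd square grid maps onto itself under 90 degrees, so the
  # rotation is interpolation-free and equals a transpose-flip
  set.seed(1)
  sq <- matrix(runif(65 * 65), 65, 65)
  r90 <- distort(sq, 90, 1)
  expect_lt(max(abs(r90 - t(sq)[, 65:1])), 1e-9)
})

test_that("inverse rotation recovers the original away from borders", {
  ph <- make_phantom(phantom_spec(class = "malignant", seed = 6,
                                  noise_sigma = 0))
  back <- distort(distort(ph$image, 33, 1), -33, 1)
  h <- nrow(ph$image)
  core <- 40:(h - 40)
  expect_lt(mean(abs(back[core, core] - ph$image[core, core])), 0.03)
})

test_that("dataset presets reproduce the published splits exactly", {
  ds1 <- make_dataset(preset = "table1", seed = 1)
  m1 <- ds1$manifest
  expect_equal(nrow(m1), 20L)
  expect_equal(sum(m1$split == "train" & m1$class == "benign"), 9L)
  expect_equal(sum(m1$split == "train" & m1$class == "malignant"), 7L)
  expect_equal(sum(m1$split == "validation" & m1$class == "benign"), 2L)
  expect_equal(sum(m1$split == "validation" & m1$class == "malignant"), 2L)
  expect_true(all(m1$angle[m1$split == "train"] != 0))  # distorted preset
  ds2 <- make_dataset(preset = "table2", seed = 1, size = c(64L, 64L))
  expect_equal(as.integer(table(ds2$manifest$split)), c(38L, 10L))
  ds3 <- make_dataset(preset = "table3", seed = 1, size = c(64L, 64L))
  expect_equal(nrow(ds3$manifest), 24L)
  expect_equal(unique(ds3$manifest$modality), "T1")
})

test_that("the manifest reproduces the dataset bit-identically", {
  ds_a <- make_dataset(train_benign = 2, train_malignant = 2,
                       val_benign = 1, val_malignant = 1,
                       distortion = "rotate", distort_split = "validation",
                       size = c(96L, 96L), seed = 7)
  ds_b <- make_dataset(train_benign = 2, train_malignant = 2,
                       val_benign = 1, val_malignant = 1,
                       distortion = "rotate", distort_split = "validation",
                       size = c(96L, 96L), seed = 7)
  expect_identical(ds_a$manifest, ds_b$manifest)
  expect_identical(ds_a$images, ds_b$images)
  # changing the master seed changes the images
  ds_c <- make_dataset(train_benign = 2, train_malignant = 2,
                       size = c(96L, 96L), seed = 8)
  expect_false(identical(ds_a$images[[1]], ds_c$images[[1]]))
})

test_that("datasets round-trip to a PNG tree with manifest", {
  d <- withr::local_tempdir()
  ds <- make_dataset(train_benign = 1, train_malignant = 1,
                     size = c(64L, 64L), seed = 3)
  write_dataset(ds, d)
  man <- utils::read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), 2L)
  img <- to_grayscale(load_image(man$path[1]))
  expect_lt(max(abs(img - ds$images[[1]])), 1 / 255 + 1e-12)
})
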