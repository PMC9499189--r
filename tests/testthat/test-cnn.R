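# Small configurations are used for the mechanical checks so they run in
# seconds; the full 224 x 224 default architecture is exercised in the
# acceptance suite.

tiny_cfg <- function(seed = 3, dropout = 0) {
  cnn_config(input_shape = c(12L, 12L, 1L), conv_filters = c(2L, 3L),
             dense_units = c(5L, 6L, 4L), dropout = dropout,
             batch_size = 2L, seed = seed)
}

test_that("shape trace follows the conv/pool arithmetic for the default net", {
  tr <- shape_trace(cnn_config())
  expect_equal(tr$out_h[tr$layer == "conv1"], 222)   # (224 - 3)/1 + 1
  expect_equal(tr$out_h[tr$layer == "pool1"], 111)   # floor((222 - 2)/2) + 1
  expect_equal(tr$out_h[tr$layer == "conv2"], 109)
  expect_equal(tr$out_h[tr$layer == "pool4"], 12)
  # closed-form parameter count, layer by layer
  expected <- (3 * 3 * 3 + 1) * 32 + (3 * 3 * 32 + 1) * 32 +
    (3 * 3 * 32 + 1) * 64 + (3 * 3 * 64 + 1) * 64 +
    (12 * 12 * 64 + 1) * 256 + (256 + 1) * 512 + (512 + 1) * 512 +
    (512 + 1) * 2
  expect_equal(sum(tr$params), expected)
  m <- build_cnn(cnn_config())
  expect_equal(count_parameters(m), expected)
  expect_error(shape_trace(cnn_config(input_shape = c(16L, 16L, 3L))),
               "below 1")
})

test_that("backpropagation matches numerical gradients", {
  m <- build_cnn(tiny_cfg())
  set.seed(10)
  img <- array(runif(144), dim = c(12, 12, 1))
  y <- c(1, 0)
  fwd <- lptbrain:::cnn_forward(m, img, keep_cache = TRUE)
  g <- lptbrain:::cnn_backward(m, fwd, y)
  loss <- function(model) {
    -log(lptbrain:::cnn_forward(model, img)$probs[1])
  }
  eps <- 1e-6
  check <- function(get, set, gval) {
    m2 <- set(m, get(m) + eps)
    num <- (loss(m2) - loss(m)) / eps
    expect_lt(abs(num - gval), 1e-3 * max(1, abs(num)))
  }
  for (l in 1:2) for (ix in sample(length(m$conv[[l]]$W), 4)) {
    check(function(mm) mm$conv[[l]]$W[ix],
          function(mm, v) { mm$conv[[l]]$W[ix] <- v; mm },
          g$conv[[l]]$W[ix])
  }
  for (d in 1:4) for (ix in sample(length(m$dense[[d]]$W), 4)) {
    check(function(mm) mm$dense[[d]]$W[ix],
          function(mm, v) { mm$dense[[d]]$W[ix] <- v; mm },
          g$dense[[d]]$W[ix])
  }
})

test_that("one RMSprop step from initialization decreases the fixed-batch loss", {
  set.seed(11)
  imgs <- lapply(1:4, function(i)
    lptbrain:::prep_input(matrix(runif(144), 12, 12), c(12L, 12L, 1L)))
  Y <- rbind(diag(2), diag(2))
  batch_loss <- function(m) {
    mean(vapply(1:4, function(i) {
      p <- lptbrain:::cnn_forward(m, imgs[[i]])$probs
      -log(max(p[which.max(Y[i, ])], 1e-12))
    }, numeric(1)))
  }
  drops <- 0
  for (s in 1:100) {
    # wide enough that no hidden layer is fully ReLU-dead at init
    m <- build_cnn(cnn_config(input_shape = c(12L, 12L, 1L),
                              conv_filters = c(4L, 4L),
                              dense_units = c(16L, 16L, 16L),
                              dropout = 0, batch_size = 4L, seed = s))
    cfg <- m$config
    vel <- list(conv = lapply(m$conv, function(l) list(W = l$W * 0, b = l$b * 0)),
                dense = lapply(m$dense, function(l) list(W = l$W * 0, b = l$b * 0)))
    acc <- NULL
    for (i in 1:4) {
      fwd <- lptbrain:::cnn_forward(m, imgs[[i]], keep_cache = TRUE)
      g <- lptbrain:::cnn_backward(m, fwd, Y[i, ])
      acc <- if (is.null(acc)) g else lptbrain:::add_grads(acc, g)
    }
    m1 <- lptbrain:::rmsprop_step(m, acc, vel, 4L, cfg)
    m1$vel <- NULL
    drops <- drops + (batch_loss(m1) < batch_loss(m))
  }
  expect_gte(drops / 100, 0.95)
})

test_that("training is seed-deterministic and dropout-free at inference", {
  set.seed(12)
  imgs <- lapply(1:6, function(i) matrix(runif(144), 12, 12))
  labs <- rep(c("benign", "malignant"), 3)
  m0 <- build_cnn(tiny_cfg(dropout = 0.5))
  m1 <- train_cnn(m0, imgs, labs, epochs = 3, seed = 5, early_stop = FALSE)
  m2 <- train_cnn(m0, imgs, labs, epochs = 3, seed = 5, early_stop = FALSE)
  expect_identical(m1$conv, m2$conv)
  expect_identical(m1$dense, m2$dense)
  expect_identical(m1$history, m2$history)
  p1 <- predict(m1, imgs[[1]])
  p2 <- predict(m1, imgs[[1]])
  expect_identical(p1, p2)
  expect_equal(sum(p1$probabilities), 1, tolerance = 1e-6)
  expect_true(p1$label %in% c("benign", "malignant"))
})

test_that("training history records per-epoch loss and accuracy", {
  set.seed(13)
  imgs <- lapply(1:4, function(i) matrix(runif(144), 12, 12))
  labs <- c("a", "b", "a", "b")
  m <- train_cnn(build_cnn(tiny_cfg()), imgs, labs, epochs = 4, seed = 2,
                 early_stop = FALSE)
  expect_equal(m$history$epoch, 1:4)
  expect_true(all(m$history$accuracy >= 0 & m$history$accuracy <= 100))
  expect_error(train_cnn(build_cnn(tiny_cfg()), imgs, rep("a", 4)),
               "class")
})
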