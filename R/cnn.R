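# A small convolutional network for binary image classification,
# implemented directly on im2col convolution kernels (src/cnn_ops.cpp).
# Default architecture: four conv(3x3, stride 1, no padding) + ReLU +
# maxpool(2, stride 2, no padding) blocks with 32/32/64/64 filters on a
# 224 x 224 x 3 input, then dense 256 (ReLU), 512 (ReLU), 512 (ReLU,
# dropout 0.5) and a 2-way softmax. Training uses RMSprop with learning
# rate 1e-5 and batch size 10, categorical cross-entropy loss, and full
# seed control over initialization, shuffling and dropout.

#' CNN configuration
#'
#' @param input_shape `(H, W, C)`; default `c(224, 224, 3)`.
#' @param conv_filters filters per conv block (default `c(32, 32, 64, 64)`).
#' @param kernel_size square conv kernel side (default 3), stride 1,
#'   no padding.
#' @param pool_size,pool_stride max-pool window and stride (default 2, 2),
#'   no padding.
#' @param dense_units hidden dense widths (default `c(256, 512, 512)`);
#'   dropout is applied after the last hidden layer.
#' @param dropout dropout probability (default 0.5).
#' @param learning_rate RMSprop learning rate (default 1e-5).
#' @param batch_size minibatch size (default 10).
#' @param epochs default training epochs (default 100).
#' @param rho,epsilon RMSprop decay and stabilizer.
#' @param n_classes output classes (default 2).
#' @param seed seed for weight initialization.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(input_shape = c(224L, 224L, 3L),
                       conv_filters = c(32L, 32L, 64L, 64L),
                       kernel_size = 3L, pool_size = 2L, pool_stride = 2L,
                       dense_units = c(256L, 512L, 512L), dropout = 0.5,
                       learning_rate = 1e-5, batch_size = 10L,
                       epochs = 100L, rho = 0.9, epsilon = 1e-8,
                       n_classes = 2L, seed = 0L) {
  structure(list(input_shape = as.integer(input_shape),
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), rho = rho, epsilon = epsilon,
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "cnn_config")
}

#' Per-layer output shapes of a CNN configuration
#'
#' Closed-form conv/pool arithmetic: a valid convolution maps `n` to
#' `n - k + 1`; a pool of size `p`, stride `s` maps `n` to
#' `floor((n - p) / s) + 1`.
#'
#' @param cfg a [cnn_config()].
#' @return data frame with columns layer, out_h, out_w, channels, params.
#' @export
shape_trace <- function(cfg) {
  h <- cfg$input_shape[1]; w <- cfg$input_shape[2]; c_in <- cfg$input_shape[3]
  k <- cfg$kernel_size; p <- cfg$pool_size; s <- cfg$pool_stride
  rows <- list(data.frame(layer = "input", out_h = h, out_w = w,
                          channels = c_in, params = 0))
  for (l in seq_along(cfg$conv_filters)) {
    f <- cfg$conv_filters[l]
    h <- h - k + 1L; w <- w - k + 1L
    if (h < 1L || w < 1L) stopf("conv block %d reduces a dimension below 1", l)
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("conv%d", l), out_h = h, out_w = w,
                 channels = f, params = (k * k * c_in + 1) * f)
    h <- (h - p) %/% s + 1L; w <- (w - p) %/% s + 1L
    if (h < 1L || w < 1L) stopf("pool block %d reduces a dimension below 1", l)
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("pool%d", l), out_h = h, out_w = w,
                 channels = f, params = 0)
    c_in <- f
  }
  n_in <- h * w * c_in
  for (m in seq_along(cfg$dense_units)) {
    u <- cfg$dense_units[m]
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("dense%d", m), out_h = 1L, out_w = 1L,
                 channels = u, params = (n_in + 1) * u)
    n_in <- u
  }
  rows[[length(rows) + 1L]] <-
    data.frame(layer = "softmax", out_h = 1L, out_w = 1L,
               channels = cfg$n_classes, params = (n_in + 1) * cfg$n_classes)
  do.call(rbind, rows)
}

#' Build an untrained CNN
#'
#' Initializes weights (He/Kaiming normal for hidden layers, scaled-down
#' normal for the softmax layer) from `cfg$seed` and records the shape
#' trace.
#'
#' @param cfg a [cnn_config()].
#' @return a `cnn4l` model object.
#' @export
build_cnn <- function(cfg = cnn_config()) {
  trace <- shape_trace(cfg)   # also validates feasibility
  k <- cfg$kernel_size
  with_seed(cfg$seed, {
    conv <- list(); c_in <- cfg$input_shape[3]
    for (l in seq_along(cfg$conv_filters)) {
      f <- cfg$conv_filters[l]
      fan_in <- k * k * c_in
      conv[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f),
        b = numeric(f))
      c_in <- f
    }
    pool_rows <- trace[grepl("^pool", trace$layer), ]
    last <- pool_rows[nrow(pool_rows), ]
    n_in <- last$out_h * last$out_w * last$channels
    dense <- list()
    widths <- c(cfg$dense_units, cfg$n_classes)
    for (m in seq_along(widths)) {
      u <- widths[m]
      sd <- if (m == length(widths)) sqrt(0.1 / n_in) else sqrt(2 / n_in)
      dense[[m]] <- list(
        W = matrix(stats::rnorm(u * n_in, sd = sd), u, n_in),
        b = numeric(u))
      n_in <- u
    }
    structure(list(config = cfg, conv = conv, dense = dense,
                   shape_trace = trace, trained = FALSE, history = NULL,
                   levels = NULL),
              class = "cnn4l")
  })
}

#' Total trainable parameter count of a CNN
#' @param model a `cnn4l`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(c(model$conv, model$dense),
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @export
print.cnn4l <- function(x, ...) {
  cat(sprintf("%d-conv-block CNN, input %s, %s parameters, %s\n",
              length(x$conv),
              paste(x$config$input_shape, collapse = "x"),
              format(count_parameters(x), big.mark = ","),
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  invisible(x)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Forward pass on one H x W x C array. train = TRUE applies inverted
# dropout using the current RNG stream. Returns probs and, if
# keep_cache, everything the backward pass needs.
cnn_forward <- function(model, img, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  k <- cfg$kernel_size
  a <- img
  cache <- if (keep_cache) list(conv = vector("list", length(model$conv)))
  for (l in seq_along(model$conv)) {
    z <- conv_fwd(a, model$conv[[l]]$W, model$conv[[l]]$b, k, k)
    r <- pmax(z, 0)
    p <- maxpool_fwd(r, cfg$pool_size, cfg$pool_stride)
    if (keep_cache)
      cache$conv[[l]] <- list(input = a, relu_pos = z > 0, relu_dim = dim(r),
                              argmax = p$argmax)
    a <- p$out
  }
  x <- as.vector(a)
  if (keep_cache) { cache$flat_dim <- dim(a); cache$acts <- list(x) }
  nd <- length(model$dense)
  drop_mask <- NULL
  for (m in seq_len(nd)) {
    z <- drop(model$dense[[m]]$W %*% x) + model$dense[[m]]$b
    if (m < nd) {
      x <- pmax(z, 0)
      if (m == nd - 1L) {     # dropout on the last hidden layer
        if (train && cfg$dropout > 0) {
          drop_mask <- (stats::runif(length(x)) >= cfg$dropout) /
            (1 - cfg$dropout)
          x <- x * drop_mask
        }
      }
      if (keep_cache) cache$acts[[m + 1L]] <- x
    } else {
      probs <- softmax(z)
    }
  }
  if (keep_cache) { cache$drop_mask <- drop_mask }
  list(probs = probs, cache = cache)
}

# Backward pass; returns gradients in the same structure as the weights.
cnn_backward <- function(model, fwd, y_onehot) {
  cfg <- model$config
  k <- cfg$kernel_size
  cache <- fwd$cache
  nd <- length(model$dense)
  gdense <- vector("list", nd)
  delta <- fwd$probs - y_onehot          # d loss / d logits
  for (m in rev(seq_len(nd))) {
    x <- cache$acts[[m]]
    gdense[[m]] <- list(W = tcrossprod(delta, x), b = delta)
    if (m > 1L) {
      delta <- drop(crossprod(model$dense[[m]]$W, delta))
      if (m - 1L == nd - 1L && !is.null(cache$drop_mask))
        delta <- delta * cache$drop_mask
      delta <- delta * (cache$acts[[m]] > 0)   # ReLU gate
    }
  }
  # into the conv stack
  delta <- drop(crossprod(model$dense[[1L]]$W, delta))
  gcube <- array(delta, dim = cache$flat_dim)
  gconv <- vector("list", length(model$conv))
  for (l in rev(seq_along(model$conv))) {
    cc <- cache$conv[[l]]
    grelu <- maxpool_bwd(cc$argmax, gcube,
                         cc$relu_dim[1], cc$relu_dim[2], cc$relu_dim[3])
    gz <- grelu * cc$relu_pos
    bk <- conv_bwd(cc$input, model$conv[[l]]$W, gz, k, k)
    gconv[[l]] <- list(W = bk$dW, b = bk$db)
    if (l > 1L) gcube <- bk$dinput
  }
  list(conv = gconv, dense = gdense)
}

# Coerce an image (matrix or H x W x C array) to the model input shape.
prep_input <- function(img, shape, auto_resize = TRUE) {
  if (is.matrix(img)) img <- array(rep(img, shape[3]), dim = c(dim(img), shape[3]))
  if (dim(img)[3] != shape[3])
    stopf("image has %d channels; model expects %d", dim(img)[3], shape[3])
  if (!all(dim(img)[1:2] == shape[1:2])) {
    if (!auto_resize)
      stopf("image is %dx%d; model expects %dx%d",
            dim(img)[1], dim(img)[2], shape[1], shape[2])
    img <- resize_image(img, shape[1], shape[2])
  }
  img
}

#' Train a CNN on labeled images
#'
#' Minibatch RMSprop with categorical cross-entropy. All randomness
#' (shuffling, dropout) comes from `seed`; weight initialization comes
#' from the config seed via [build_cnn()]. After each epoch the training
#' set is re-evaluated in inference mode (dropout off) and loss/accuracy
#' are recorded; with `early_stop = TRUE` training stops once training
#' accuracy reaches 100%.
#'
#' @param model an untrained (or trained) `cnn4l`.
#' @param images list of grayscale matrices or `H x W x C` arrays in
#'   `[0, 1]`; grayscale images are replicated to the input channel
#'   count, and sizes are adapted by bilinear resize.
#' @param labels factor/character labels, one per image, 2 classes.
#' @param epochs training epochs (default: config value).
#' @param seed seed for shuffling and dropout.
#' @param early_stop stop when training accuracy reaches 100%
#'   (default `TRUE`).
#' @param verbose print per-epoch progress.
#' @return the trained `cnn4l` with a `history` data frame
#'   (epoch, loss, accuracy).
#' @export
train_cnn <- function(model, images, labels, epochs = NULL, seed = 0L,
                      early_stop = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "cnn4l"))
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  y <- factor(labels)
  if (nlevels(y) != 2L && nlevels(y) != cfg$n_classes)
    stopf("expected %d classes, got %d", cfg$n_classes, nlevels(y))
  if (any(tabulate(y, nlevels(y)) == 0L)) stopf("every class needs examples")
  n <- length(images)
  if (n != length(y)) stopf("images and labels differ in length")
  shape <- cfg$input_shape
  X <- lapply(images, prep_input, shape = shape)
  Y <- diag(cfg$n_classes)[as.integer(y), , drop = FALSE]

  # RMSprop accumulators, zero-initialized, same structure as weights
  vel <- list(conv = lapply(model$conv, function(l)
                list(W = l$W * 0, b = l$b * 0)),
              dense = lapply(model$dense, function(l)
                list(W = l$W * 0, b = l$b * 0)))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        batch <- idx[start:min(start + cfg$batch_size - 1L, n)]
        acc <- NULL
        for (i in batch) {
          fwd <- cnn_forward(model, X[[i]], train = TRUE, keep_cache = TRUE)
          g <- cnn_backward(model, fwd, Y[i, ])
          acc <- if (is.null(acc)) g else add_grads(acc, g)
        }
        model <- rmsprop_step(model, acc, vel, length(batch), cfg)
        vel <- model$vel; model$vel <- NULL
      }
      ev <- vapply(seq_len(n), function(i) {
        p <- cnn_forward(model, X[[i]])$probs
        c(-log(max(p[which.max(Y[i, ])], 1e-12)),
          as.numeric(which.max(p) == which.max(Y[i, ])))
      }, numeric(2))
      history <- rbind(history,
                       data.frame(epoch = ep, loss = mean(ev[1, ]),
                                  accuracy = 100 * mean(ev[2, ])))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.1f%%",
                        ep, mean(ev[1, ]), 100 * mean(ev[2, ])))
      if (early_stop && mean(ev[2, ]) == 1) break
    }
  })
  model$trained <- TRUE
  model$history <- history
  model$levels <- levels(y)
  model
}

add_grads <- function(a, g) {
  for (l in seq_along(a$conv)) {
    a$conv[[l]]$W <- a$conv[[l]]$W + g$conv[[l]]$W
    a$conv[[l]]$b <- a$conv[[l]]$b + g$conv[[l]]$b
  }
  for (m in seq_along(a$dense)) {
    a$dense[[m]]$W <- a$dense[[m]]$W + g$dense[[m]]$W
    a$dense[[m]]$b <- a$dense[[m]]$b + g$dense[[m]]$b
  }
  a
}

rmsprop_step <- function(model, grad, vel, batch_n, cfg) {
  upd <- function(w, g, v) {
    g <- g / batch_n
    v <- cfg$rho * v + (1 - cfg$rho) * g^2
    list(w = w - cfg$learning_rate * g / (sqrt(v) + cfg$epsilon), v = v)
  }
  for (l in seq_along(model$conv)) {
    uW <- upd(model$conv[[l]]$W, grad$conv[[l]]$W, vel$conv[[l]]$W)
    ub <- upd(model$conv[[l]]$b, grad$conv[[l]]$b, vel$conv[[l]]$b)
    model$conv[[l]]$W <- uW$w; vel$conv[[l]]$W <- uW$v
    model$conv[[l]]$b <- ub$w; vel$conv[[l]]$b <- ub$v
  }
  for (m in seq_along(model$dense)) {
    uW <- upd(model$dense[[m]]$W, grad$dense[[m]]$W, vel$dense[[m]]$W)
    ub <- upd(model$dense[[m]]$b, grad$dense[[m]]$b, vel$dense[[m]]$b)
    model$dense[[m]]$W <- uW$w; vel$dense[[m]]$W <- uW$v
    model$dense[[m]]$b <- ub$w; vel$dense[[m]]$b <- ub$v
  }
  model$vel <- vel
  model
}

#' Classify an image with a trained CNN
#'
#' Inference-mode forward pass (dropout disabled, deterministic). The
#' class probabilities are the softmax outputs and sum to 1.
#'
#' @param object a trained `cnn4l`.
#' @param img grayscale matrix or `H x W x C` array.
#' @param auto_resize adapt the image to the input shape (default `TRUE`).
#' @param ... unused.
#' @return list with `label` and named `probabilities`.
#' @export
predict.cnn4l <- function(object, img, auto_resize = TRUE, ...) {
  if (!isTRUE(object$trained)) stopf("model is untrained; call train_cnn() first")
  x <- prep_input(img, object$config$input_shape, auto_resize = auto_resize)
  p <- cnn_forward(object, x)$probs
  lev <- object$levels
  if (is.null(lev)) lev <- paste0("class", seq_along(p))
  names(p) <- lev
  list(label = lev[which.max(p)], probabilities = p)
}
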