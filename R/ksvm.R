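# Kernel SVM classification. The package computes the four kernels
# (linear, RBF, polynomial, quadratic) itself; the soft-margin dual
# problem is solved by kernlab's SMO on the precomputed kernel matrix.
# Features are z-scored with training-set statistics before any kernel
# evaluation.

#' Kernel specification
#'
#' @param kind one of `"linear"`, `"rbf"`, `"polynomial"`, `"quadratic"`.
#' @param gamma RBF width; `NULL` (default) means `1 / (d * var(X))`
#'   computed from the training data at fit time.
#' @param degree polynomial degree (default 3; `quadratic` fixes 2).
#' @param coef0 polynomial offset (default 1).
#' @param C soft-margin cost (default 1).
#' @return a `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("rbf", "linear", "polynomial", "quadratic"),
                        gamma = NULL, degree = 3L, coef0 = 1, C = 1) {
  kind <- match.arg(kind)
  degree <- as.integer(if (kind == "quadratic") 2L else degree)
  if (degree < 1L) stopf("`degree` must be >= 1")
  if (!is.null(gamma) && gamma <= 0) stopf("`gamma` must be positive")
  if (C <= 0) stopf("`C` must be positive")
  structure(list(kind = kind, gamma = gamma, degree = degree,
                 coef0 = coef0, C = C),
            class = "kernel_spec")
}

#' Kernel matrix between two sets of feature rows
#'
#' linear: `x . y`; rbf: `exp(-gamma ||x - y||^2)`; polynomial:
#' `(x . y + coef0)^degree`; quadratic: polynomial with degree 2.
#'
#' @param X,Y numeric matrices with the same number of columns.
#' @param spec a [kernel_spec()]. A `NULL` `gamma` defaults to
#'   `1 / (ncol(X) * var(X))` with `var` the total variance of `X`.
#' @return `nrow(X) x nrow(Y)` matrix.
#' @export
kernel_matrix <- function(X, Y = X, spec = kernel_spec("linear")) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stopf("X and Y must have the same number of columns")
  ip <- X %*% t(Y)
  switch(spec$kind,
    linear = ip,
    rbf = {
      g <- spec$gamma
      if (is.null(g)) g <- default_gamma(X)
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * ip
      d2[d2 < 0] <- 0
      exp(-g * d2)
    },
    polynomial = (ip + spec$coef0)^spec$degree,
    quadratic = (ip + spec$coef0)^2)
}

default_gamma <- function(X) {
  v <- mean(apply(X, 2, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

#' Train a kernel SVM on a feature matrix
#'
#' Z-scores the columns with training statistics, builds the kernel
#' matrix with [kernel_matrix()], and solves the soft-margin dual with
#' kernlab's SMO. Binary tasks only (e.g. benign/malignant or
#' normal/abnormal).
#'
#' @param X numeric `n x d` feature matrix.
#' @param labels factor or character vector of length `n`, 2 classes.
#' @param spec a [kernel_spec()].
#' @return a `ksvm_model` with the support vectors, dual coefficients,
#'   bias, kernel spec and scaling, usable with `predict()` and
#'   [evaluate_accuracy()].
#' @export
train_ksvm <- function(X, labels, spec = kernel_spec("rbf")) {
  X <- as.matrix(X)
  y <- factor(labels)
  if (nlevels(y) != 2L) stopf("exactly 2 classes required (got %d)", nlevels(y))
  if (nrow(X) != length(y)) stopf("nrow(X) must match length(labels)")
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[!is.finite(sds) | sds < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  if (spec$kind == "rbf" && is.null(spec$gamma)) spec$gamma <- default_gamma(Z)
  K <- kernel_matrix(Z, Z, spec)
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc",
                       C = spec$C, tol = 1e-4)
  sv <- kernlab::SVindex(fit)
  structure(list(fit = fit, spec = spec, center = ctr, scale = sds,
                 X_train = Z, sv_index = sv,
                 dual_coef = kernlab::coef(fit), bias = kernlab::b(fit),
                 levels = levels(y), n_features = ncol(X)),
            class = "ksvm_model")
}

#' @export
print.ksvm_model <- function(x, ...) {
  cat(sprintf("kernel SVM (%s kernel, C = %g): %d support vectors, classes %s/%s\n",
              x$spec$kind, x$spec$C, length(x$sv_index),
              x$levels[1], x$levels[2]))
  invisible(x)
}

#' @export
predict.ksvm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stopf("newdata has %d columns; model expects %d",
          ncol(newdata), object$n_features)
  Z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  Kp <- kernel_matrix(Z, object$X_train, object$spec)
  pred <- kernlab::predict(
    object$fit,
    kernlab::as.kernelMatrix(Kp[, object$sv_index, drop = FALSE]))
  factor(as.character(pred), levels = object$levels)
}

#' Classification accuracy of a model on a validation set
#'
#' @param model a `ksvm_model` (or any object with a compatible
#'   `predict` method returning class labels).
#' @param X validation feature matrix with the training schema.
#' @param labels true labels.
#' @return accuracy as a percentage in `[0, 100]`.
#' @export
evaluate_accuracy <- function(model, X, labels) {
  pred <- predict(model, X)
  100 * mean(as.character(pred) == as.character(labels))
}
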