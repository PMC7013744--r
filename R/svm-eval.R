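#' Radial basis function kernel
#'
#' `K(x, x') = exp(-||x - x'||^2 / (2 sigma2))`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param sigma2 Positive kernel width parameter.
#' @return Numeric in `(0, 1]`.
#' @export
rbf_kernel <- function(x, y, sigma2) {
  if (length(x) != length(y)) {
    stop_invalid("kernel arguments differ in dimension")
  }
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop_invalid("sigma2 must be positive")
  }
  exp(-sum((x - y)^2) / (2 * sigma2))
}

#' Classifier configuration
#'
#' @param sigma2 RBF kernel width; `"auto"` uses half the median squared
#'   pairwise distance of the training points.
#' @param cost Soft-margin regularization constant C.
#' @param folds Number of cross-validation folds.
#' @param fold_seed Seed for the stratified fold assignment.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(sigma2 = "auto", cost = 1, folds = 5L,
                       fold_seed = 1L) {
  stopifnot(cost > 0, folds >= 2)
  if (!identical(sigma2, "auto")) stopifnot(is.numeric(sigma2), sigma2 > 0)
  structure(list(sigma2 = sigma2, cost = cost, folds = as.integer(folds),
                 fold_seed = as.integer(fold_seed)),
            class = "svm_config")
}

# Median-heuristic kernel width on (a deterministic subsample of) x.
auto_sigma2 <- function(x, max_points = 200L) {
  n <- nrow(x)
  if (n > max_points) {
    x <- x[round(seq(1, n, length.out = max_points)), , drop = FALSE]
  }
  d2 <- stats::dist(x)^2
  max(stats::median(d2) / 2, 1e-6)
}

#' Train a soft-margin RBF support vector machine
#'
#' Thin wrapper around the libsvm solver in \pkg{e1071}; the decision
#' function is the usual signed kernel expansion over the support
#' vectors.  Inputs are used as-is (no internal rescaling), so features
#' should be standardized beforehand (see [scale_features()]).
#'
#' @param x Numeric matrix of predictors (rows = samples).
#' @param y Two-level factor of class labels.
#' @param config An [svm_config()].
#' @return Object of class `uniftex_svm` with elements `model` (the
#'   fitted solver object), `sigma2` (width actually used) and `config`.
#' @export
svm_train <- function(x, y, config = svm_config()) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2L || any(table(y) == 0)) {
    stop_invalid("training data must contain both classes")
  }
  sigma2 <- if (identical(config$sigma2, "auto")) auto_sigma2(x) else
    config$sigma2
  model <- e1071::svm(x, y, kernel = "radial", gamma = 1 / (2 * sigma2),
                      cost = config$cost, scale = FALSE, fitted = FALSE)
  structure(list(model = model, sigma2 = sigma2, config = config),
            class = "uniftex_svm")
}

#' @export
predict.uniftex_svm <- function(object, newdata, ...) {
  stats::predict(object$model, as.matrix(newdata), ...)
}

#' Stratified cross-validation folds
#'
#' Assigns samples to `k` folds so that fold sizes differ by at most one
#' and each class is spread as evenly as possible across folds.  The
#' assignment is deterministic for a fixed seed and leaves the caller's
#' RNG stream untouched.
#'
#' @param y Factor of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
make_stratified_folds <- function(y, k, seed = 1L) {
  y <- factor(y)
  if (any(table(y) < k)) {
    stop_invalid("every class needs at least k = ", k, " samples")
  }
  fold <- integer(length(y))
  with_seed(seed, {
    counter <- 0L
    for (cl in levels(y)) {
      idx <- resample(which(y == cl), sum(y == cl))
      fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
      counter <- counter + length(idx)
    }
  })
  fold
}

#' Cross-validated SVM accuracy
#'
#' Stratified k-fold cross-validation of the RBF SVM on the given
#' feature matrix; the mean of the per-fold accuracies is the accuracy
#' statistic consumed by both the filter stage and the wrapper fitness.
#'
#' @inheritParams svm_train
#' @return Object of class `cv_result`: list with `fold_accuracy`,
#'   `mean_accuracy`, `folds` (the assignment) and `config`.
#' @export
svm_cross_validate <- function(x, y, config = svm_config()) {
  x <- as.matrix(x)
  y <- factor(y)
  if (identical(config$sigma2, "auto")) {
    # resolve the median-heuristic width once for all folds
    config$sigma2 <- auto_sigma2(x)
  }
  folds <- make_stratified_folds(y, config$folds, config$fold_seed)
  acc <- vapply(seq_len(config$folds), function(f) {
    train <- folds != f
    fit <- svm_train(x[train, , drop = FALSE], y[train], config)
    pred <- predict(fit, x[!train, , drop = FALSE])
    mean(pred == y[!train])
  }, numeric(1))
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 folds = folds, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated accuracy:", format(x$mean_accuracy, digits = 4),
      "(", length(x$fold_accuracy), "folds )\n")
  invisible(x)
}
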