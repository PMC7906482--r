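#' Train the stem/leaf point classifier
#'
#' Fits a support vector machine (RBF kernel, via \pkg{e1071}) on per-point
#' features from [compute_features()]. Features are standardized internally by
#' the SVM. Both classes must be present in the training labels.
#'
#' @param features numeric feature matrix (one row per point).
#' @param labels character vector of `"stem"`/`"leaf"` training labels.
#' @param cost SVM soft-margin cost.
#' @param gamma RBF kernel width; `NULL` uses the 1/ncol heuristic.
#' @param seed RNG seed (training is deterministic; the seed fixes any
#'   sampling done by cross-validation helpers).
#' @return an object of class `point_classifier` with the fitted model, the
#'   feature width, and the training accuracy.
#' @export
train_classifier <- function(features, labels, cost = 1, gamma = NULL, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("training labels must contain both classes")
  if (nrow(features) != length(labels))
    stop("one label per feature row required")
  set.seed(seed)
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  fit <- e1071::svm(x = features, y = factor(labels, levels = c("stem", "leaf")),
                    kernel = "radial", cost = cost, gamma = gamma, scale = TRUE)
  train_pred <- as.character(stats::predict(fit, features))
  structure(list(model = fit, n_features = ncol(features),
                 train_accuracy = mean(train_pred == labels)),
            class = "point_classifier")
}

#' @export
print.point_classifier <- function(x, ...) {
  cat(sprintf("point_classifier: SVM on %d features, training accuracy %.3f\n",
              x$n_features, x$train_accuracy))
  invisible(x)
}

#' Predict stem/leaf classes for point features
#'
#' @param model a `point_classifier` from [train_classifier()].
#' @param features feature matrix with the same width used in training.
#' @return character vector of per-point classes.
#' @export
classify_points <- function(model, features) {
  stopifnot(inherits(model, "point_classifier"))
  if (ncol(features) != model$n_features)
    stop(sprintf("feature width %d does not match training width %d",
                 ncol(features), model$n_features))
  as.character(stats::predict(model$model, features))
}
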