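#' Gradient-boosted decision trees (histogram-based, leaf-wise)
#'
#' A compact in-package Newton-boosting learner in the style of LightGBM's
#' `gbdt`: quantile-binned features, best-first tree growth to `num_leaves`
#' leaves, second-order split gain with L2 damping.  Deterministic given its
#' inputs.  It backs both the cardiogenic-shock classifier (binary logistic
#' loss with optional balanced class weights) and the conditional models of
#' the chained-equation imputer (squared-error regression).
#'
#' @param X numeric matrix of features (complete; no `NA`).
#' @param y numeric response; for `objective = "binary"` a 0/1 vector.
#' @param objective `"binary"` or `"regression"`.
#' @param weights optional per-sample weights.
#' @param class_weight `"none"` or `"balanced"`; balanced rescales each
#'   class inversely to its frequency (`n / (2 n_c)`), multiplied into
#'   `weights`.  Binary objective only.
#' @param n_estimators number of boosting rounds (default 100).
#' @param num_leaves maximum leaves per tree (default 31).
#' @param learning_rate shrinkage (default 0.1).
#' @param min_data_in_leaf minimum samples per leaf (default 20).
#' @param lambda_l2 L2 regularisation on leaf values (default 0).
#' @param max_bin maximum histogram bins per feature (default 255).
#' @return object of class `shockpipe_gbt`.
#' @export
gbt_fit <- function(X, y, objective = c("binary", "regression"),
                    weights = NULL, class_weight = c("none", "balanced"),
                    n_estimators = 100L, num_leaves = 31L,
                    learning_rate = 0.1, min_data_in_leaf = 20L,
                    lambda_l2 = 0, max_bin = 255L) {
  objective <- match.arg(objective)
  class_weight <- match.arg(class_weight)
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (objective == "binary") {
    if (!all(y %in% c(0, 1))) stop("binary objective needs 0/1 labels")
    if (length(unique(y)) < 2) stop("single-class response")
    if (class_weight == "balanced") {
      n <- length(y)
      w <- w * ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
    }
  }
  min_data_in_leaf <- min(as.integer(min_data_in_leaf),
                          max(1L, nrow(X) %/% 4L))
  model <- .gbt_train(X, y, objective, w, as.integer(n_estimators),
                      as.integer(num_leaves), learning_rate,
                      min_data_in_leaf, lambda_l2, as.integer(max_bin))
  structure(list(model = model, p = ncol(X), objective = objective),
            class = "shockpipe_gbt")
}

#' @param object a `shockpipe_gbt` model.
#' @param newdata numeric matrix with the training column layout.
#' @param type `"response"` (probability for binary, mean for regression)
#'   or `"raw"` (boosted score before the link).
#' @param ... unused.
#' @rdname gbt_fit
#' @export
predict.shockpipe_gbt <- function(object, newdata,
                                  type = c("response", "raw"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata); storage.mode(newdata) <- "double"
  stopifnot(ncol(newdata) == object$p)
  f <- .gbt_predict_raw(object$model, newdata)
  if (type == "raw" || object$objective == "regression") return(f)
  1 / (1 + exp(-f))
}

#' Model factories for the chained-equation imputer
#'
#' The imputer's conditional-model contract is
#' `model_factory(X, y) -> list(predict = function(X) ...)`.  These
#' factories wrap [gbt_fit()]: `gbt_regressor` returns predicted means for
#' predictive mean matching on continuous targets; `gbt_classifier` fits a
#' one-vs-rest boosted model per level of a factor target and returns a
#' normalised probability matrix (columns = levels).
#'
#' @param n_estimators,num_leaves,min_data_in_leaf,max_bin capacity
#'   controls; conditional models default lighter than the final classifier.
#' @return a factory `function(X, y)`.
#' @export
gbt_regressor <- function(n_estimators = 30L, num_leaves = 15L,
                          min_data_in_leaf = 10L, max_bin = 64L) {
  function(X, y) {
    fit <- gbt_fit(X, y, objective = "regression",
                   n_estimators = n_estimators, num_leaves = num_leaves,
                   min_data_in_leaf = min_data_in_leaf, max_bin = max_bin)
    list(predict = function(Xn) predict(fit, Xn))
  }
}

#' @rdname gbt_regressor
#' @export
gbt_classifier <- function(n_estimators = 30L, num_leaves = 15L,
                           min_data_in_leaf = 10L, max_bin = 64L) {
  function(X, y) {
    y <- as.factor(y)
    lv <- levels(droplevels(y))
    fits <- lapply(lv, function(l) {
      yy <- as.numeric(y == l)
      if (length(unique(yy)) < 2) return(mean(yy))  # degenerate level
      gbt_fit(X, yy, objective = "binary",
              n_estimators = n_estimators, num_leaves = num_leaves,
              min_data_in_leaf = min_data_in_leaf, max_bin = max_bin)
    })
    list(levels = lv, predict = function(Xn) {
      P <- vapply(fits, function(f) {
        if (is.numeric(f)) rep(f, nrow(Xn)) else predict(f, Xn)
      }, numeric(nrow(Xn)))
      P <- matrix(P, nrow = nrow(Xn), dimnames = list(NULL, lv))
      P / pmax(rowSums(P), 1e-12)
    })
  }
}
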