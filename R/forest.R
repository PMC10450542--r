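# In-package CART forest (no tree-learner package ships in the target
# environment). Binary responses give probability trees whose impurity
# (variance) gain equals Gini gain up to a constant, so `importance` is the
# familiar impurity-based measure, normalized to sum to 1.

#' Fit a random forest / extra-trees ensemble
#'
#' @param X Numeric matrix (rows = samples).
#' @param y Binary response (0/1, logical, or factor with 2 levels) for
#'   classification, or any numeric vector for regression trees.
#' @param ntree Number of trees.
#' @param mtry Features tried per split; default `floor(sqrt(p))` for
#'   forests, `p` for a single tree.
#' @param max_depth Maximum tree depth.
#' @param min_node Minimum samples per leaf.
#' @param bootstrap Bootstrap-resample rows per tree (TRUE for random
#'   forests, FALSE for extra-trees).
#' @param random_split Draw one uniform threshold per candidate feature
#'   (extra-trees) instead of exhaustive search.
#' @param weights Optional nonnegative sample weights.
#' @return An `am_forest` with elements `trees`, `importance` (normalized),
#'   `importance_raw`.
#' @export
am_forest <- function(X, y, ntree = 100L, mtry = NULL, max_depth = 10L,
                      min_node = 1L, bootstrap = TRUE, random_split = FALSE,
                      weights = NULL, oob_importance = FALSE) {
  X <- as.matrix(X)
  y <- as_binary01(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  if (is.null(weights)) weights <- rep(1, nrow(X))
  fit <- cpp_grow_forest(X, as.numeric(y), as.numeric(weights),
                         as.integer(ntree), as.integer(mtry),
                         as.integer(max_depth), as.integer(min_node),
                         isTRUE(bootstrap), isTRUE(random_split),
                         isTRUE(oob_importance))
  fit$features <- colnames(X)
  names(fit$importance) <- colnames(X)
  names(fit$importance_raw) <- colnames(X)
  names(fit$importance_oob) <- colnames(X)
  class(fit) <- "am_forest"
  fit
}

#' Fit a single decision tree
#' @inheritParams am_forest
#' @return An `am_forest` with one tree.
#' @export
am_tree <- function(X, y, max_depth = 6L, min_node = 2L) {
  am_forest(X, y, ntree = 1L, mtry = ncol(as.matrix(X)),
            max_depth = max_depth, min_node = min_node, bootstrap = FALSE)
}

#' @param object An `am_forest`.
#' @param newdata Matrix to predict.
#' @param ... Unused.
#' @return Mean leaf value per row (class-1 probability for 0/1 training
#'   response).
#' @rdname am_forest
#' @export
predict.am_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features))
    newdata <- newdata[, object$features, drop = FALSE]
  cpp_predict_forest(object$trees, newdata)
}

as_binary01 <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y)) stop("character response; use a factor or 0/1")
  as.numeric(y)
}
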