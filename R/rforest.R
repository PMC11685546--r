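#' Fit a CART random forest
#'
#' Bootstrap-bagged CART trees with Gini splits and per-node random feature
#' subsampling (`mtry`), the classical random-forest recipe. Class
#' probabilities are the across-tree average of leaf class proportions, and
#' feature importance is mean decrease in impurity (MDI). Implemented in
#' compiled code inside this package because the runtime environment carries
#' no random-forest library; it is the companion "classical" model of the
#' ensemble and the engine behind [importance_rank()].
#'
#' @param x Numeric matrix or data frame of predictors (rows = segments).
#' @param y Class labels (factor or coercible).
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param min_split Minimum node size to attempt a split.
#' @param max_depth Depth cap.
#' @param seed Integer seed; the forest is deterministic given seed and input
#'   order.
#' @return An object of class `har_rf` with `predict` and [rf_importance()]
#'   support.
#' @export
rf_fit <- function(x, y, ntree = 500, mtry = NULL, min_split = 2,
                   max_depth = 25, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  check(nrow(x) == length(y), "rf_fit: x and y sizes differ")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (nlevels(y) == 1) {
    # degenerate single-class forest: all probability mass on the one class
    return(structure(list(trees = list(), importance_raw = rep(0, ncol(x)),
                          classes = levels(y), features = colnames(x),
                          ntree = 0L, mtry = mtry, seed = seed),
                     class = "har_rf"))
  }
  seeds <- with_seed(seed, sample.int(2147483646L, ntree))
  fit <- .cpp_grow_forest(x, as.integer(y) - 1L, nlevels(y), as.integer(ntree),
                          as.integer(mtry), as.integer(min_split),
                          as.integer(max_depth), seeds)
  structure(list(trees = fit$trees, importance_raw = fit$importance,
                 classes = levels(y), features = colnames(x),
                 ntree = ntree, mtry = mtry, seed = seed),
            class = "har_rf")
}

#' @export
print.har_rf <- function(x, ...) {
  cat(sprintf("<har_rf> %d trees, mtry %d, %d features, classes: %s\n",
              x$ntree, x$mtry, length(x$features), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @param object,newdata,type Standard predict arguments; `type` is
#'   `"prob"` (class-probability matrix, rows sum to 1) or `"class"`.
#' @param ... Unused.
#' @rdname rf_fit
#' @export
predict.har_rf <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(newdata) <- "double"
  pr <- if (length(object$trees) == 0) {
    matrix(1, nrow(newdata), length(object$classes))
  } else {
    .cpp_predict_forest(object$trees, newdata, length(object$classes))
  }
  colnames(pr) <- object$classes
  if (type == "prob") return(pr)
  factor(object$classes[max.col(pr, ties.method = "first")], levels = object$classes)
}

#' Mean-decrease-in-impurity feature importance
#'
#' @param object A fitted [rf_fit()] forest.
#' @return Named non-negative vector summing to 1 (uniform if the forest never
#'   split).
#' @export
rf_importance <- function(object) {
  imp <- object$importance_raw
  s <- sum(imp)
  imp <- if (s > 0) imp / s else rep(1 / length(imp), length(imp))
  stats::setNames(imp, object$features)
}
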