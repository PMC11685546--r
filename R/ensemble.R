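#' Classification metrics and confusion matrix
#'
#' Accuracy is correct/total; precision, recall and F1 are macro-averaged
#' over classes (per-class ratios with empty denominators counted as 0).
#' Confusion-matrix rows are true classes, columns predicted classes.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Canonical class order; default the sorted union.
#' @return Object of class `har_eval` with fields `accuracy`, `precision`,
#'   `recall`, `f1` (proportions in `[0, 1]`), `per_class`, `confusion`.
#' @export
compute_metrics <- function(y_true, y_pred, classes = NULL) {
  check(length(y_true) > 0, "compute_metrics: empty input")
  check(length(y_true) == length(y_pred), "compute_metrics: length mismatch")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  cm <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  tp <- diag(cm)
  ratio0 <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- ratio0(tp, colSums(cm))
  rec <- ratio0(tp, rowSums(cm))
  f1 <- ratio0(2 * prec * rec, prec + rec)
  structure(list(accuracy = sum(tp) / length(y_true),
                 precision = mean(prec), recall = mean(rec), f1 = mean(f1),
                 per_class = data.frame(class = classes, precision = as.numeric(prec),
                                        recall = as.numeric(rec), f1 = as.numeric(f1),
                                        support = as.numeric(rowSums(cm))),
                 confusion = unclass(cm), n = length(y_true)),
            class = "har_eval")
}

#' @export
print.har_eval <- function(x, ...) {
  cat(sprintf("<har_eval> n = %d | accuracy %.1f%% | precision %.1f%% | recall %.1f%% | F1 %.1f%%\n",
              x$n, 100 * x$accuracy, 100 * x$precision, 100 * x$recall, 100 * x$f1))
  if (!is.null(x$fold_accuracy)) {
    cat("  per-fold accuracy:",
        paste(sprintf("%s=%.2f", names(x$fold_accuracy), x$fold_accuracy),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.har_eval <- function(x, ...) {
  cm <- x$confusion
  graphics::image(seq_len(ncol(cm)), seq_len(nrow(cm)), t(cm[rev(seq_len(nrow(cm))), ]),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  col = grDevices::hcl.colors(25, "Blues 3", rev = TRUE), ...)
  graphics::axis(1, seq_len(ncol(cm)), colnames(cm))
  graphics::axis(2, seq_len(nrow(cm)), rev(rownames(cm)), las = 2)
  for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
    graphics::text(j, nrow(cm) - i + 1, cm[i, j])
  }
  invisible(x)
}

#' Weighted-probability decision fusion
#'
#' Computes the weighted sum of class-probability matrices,
#' `S = sum_i beta_i P_i`, and predicts the argmax class per sample; ties are
#' broken toward the lowest class index. Weights need not be normalised
#' (the argmax is scale-invariant).
#'
#' @param probs List of probability matrices, congruent in shape and class
#'   (column) order.
#' @param weights Non-negative weights, one per matrix, at least one positive.
#'   The validated default is 2 for the stacked CNN and 1 for the random
#'   forest.
#' @return Factor of predicted labels, with the fused score matrix in
#'   attribute `"scores"`.
#' @export
#' @examples
#' p1 <- matrix(c(0.6, 0.4), 1)  # model 1: A 0.6, B 0.4
#' p2 <- matrix(c(0.0, 1.0), 1)  # model 2: A 0.0, B 1.0
#' colnames(p1) <- colnames(p2) <- c("A", "B")
#' fuse(list(p1, p2), weights = c(2, 1))  # B: 1.8 beats A: 1.2
fuse <- function(probs, weights) {
  check(length(probs) >= 1 && length(weights) == length(probs),
        "fuse: need one weight per probability matrix")
  check(all(weights >= 0) && any(weights > 0),
        "fuse: weights must be non-negative with at least one positive")
  ref <- colnames(probs[[1]])
  for (p in probs[-1]) {
    check(all(dim(p) == dim(probs[[1]])), "fuse: probability matrices differ in shape")
    check(identical(colnames(p), ref), "fuse: class order differs between models")
  }
  S <- Reduce(`+`, Map(function(p, w) w * p, probs, weights))
  idx <- max.col(S, ties.method = "first")
  out <- factor(ref[idx], levels = ref)
  attr(out, "scores") <- S
  out
}

#' Configuration of the full recognition pipeline
#'
#' @param augment `NULL` (off) or an [augmentation_plan()]; applied to
#'   training data only, grouping by the prediction target.
#' @param scnn An [scnn_config()], or `NULL` to drop the CNN path.
#' @param rf `NULL` to drop the forest path, else a list of [rf_fit()]
#'   settings (`ntree`, `mtry`, ...).
#' @param select `"none"`, `"prune"` (correlation pruning) or `"saturation"`
#'   (pruning + importance ranking + saturation-curve cut).
#' @param prune_threshold,epsilon,rank_ntree Selection settings.
#' @param weights Fusion weights, named `scnn` and `rf`.
#' @param filter Median+Butterworth filtering before feature extraction.
#' @param seed Root seed; all stage seeds are derived from it.
#' @return Object of class `har_config`.
#' @export
har_config <- function(augment = NULL, scnn = scnn_config(), rf = list(ntree = 300),
                       select = c("prune", "none", "saturation"),
                       prune_threshold = 0.9, epsilon = 0.005, rank_ntree = 300,
                       weights = c(scnn = 2, rf = 1), filter = TRUE, seed = 1) {
  select <- match.arg(select)
  check(!is.null(scnn) || !is.null(rf), "har_config: need at least one model")
  structure(list(augment = augment, scnn = scnn, rf = rf, select = select,
                 prune_threshold = prune_threshold, epsilon = epsilon,
                 rank_ntree = rank_ntree, weights = weights, filter = filter,
                 seed = as.integer(seed)), class = "har_config")
}

#' Fit the stacked-CNN + random-forest ensemble
#'
#' Runs the training half of the recognition system on a segment set:
#' optional class-balancing augmentation, feature extraction (filtering,
#' 13-channel intermediate features, 117 statistical features), optional
#' feature selection, a random forest on the statistical features, a stacked
#' CNN on the acceleration + angle channels, and weighted-probability fusion
#' at prediction time.
#'
#' @param set Training `har_segmentset`.
#' @param target `"activity"` (activity recognition) or `"user"` (nurse
#'   identification).
#' @param config A [har_config()].
#' @return Object of class `har_ensemble` with `predict`, `print`, `summary`
#'   methods. Provenance fields record exactly which segment uids entered
#'   augmentation, selection and each model fit.
#' @export
har_fit <- function(set, target = c("activity", "user"), config = har_config()) {
  target <- match.arg(target)
  check(length(set) > 0, "har_fit: empty training set")
  original_uids <- segment_uids(set)
  classes <- sort(unique(if (target == "activity") activities(set) else users(set)))
  check(length(classes) >= 2, "har_fit: need at least 2 classes")

  aug_parents <- character(0)
  if (!is.null(config$augment)) {
    set <- balance_augment(set, config$augment, by = target)
    is_aug <- vapply(set$segments, function(s) s$source_id != "original", logical(1))
    aug_parents <- vapply(set$segments[is_aug], `[[`, character(1), "parent_uid")
  }
  labels <- factor(if (target == "activity") activities(set) else users(set),
                   levels = classes)

  rf_model <- NULL; selection <- NULL; rf_features <- NULL
  tab <- NULL
  if (!is.null(config$rf) || config$select != "none") {
    tab <- build_feature_table(set, filter = config$filter)
  }
  selection_uids <- character(0)
  if (config$select != "none") {
    pruned <- correlation_prune(tab, threshold = config$prune_threshold)
    selection_uids <- tab$segment_uid
    rf_features <- feature_columns(pruned)
    if (config$select == "saturation") {
      ranked <- importance_rank(pruned, target = target,
                                forest_seed = derive_seed(config$seed, "rank"),
                                ntree = config$rank_ntree)
      selection <- saturation_select(ranked, pruned, target = target,
                                     epsilon = config$epsilon,
                                     seed = derive_seed(config$seed, "satsel"))
      rf_features <- selection$selected
    }
  } else if (!is.null(tab)) {
    rf_features <- feature_columns(tab)
  }

  if (!is.null(config$rf)) {
    rf_model <- do.call(rf_fit, c(list(x = as.matrix(tab[, rf_features, drop = FALSE]),
                                       y = labels,
                                       seed = derive_seed(config$seed, "rf")),
                                  config$rf))
  }

  scnn_model <- NULL
  if (!is.null(config$scnn)) {
    sc <- config$scnn
    sc$seed <- derive_seed(config$seed, "scnn")
    scnn_model <- scnn_fit(set, y = labels, config = sc, filter = config$filter)
  }

  structure(list(rf = rf_model, scnn = scnn_model, weights = config$weights,
                 classes = classes, target = target, config = config,
                 rf_features = rf_features, selection = selection,
                 provenance = list(original_uids = original_uids,
                                   train_uids = segment_uids(set),
                                   aug_parent_uids = unique(as.character(aug_parents)),
                                   selection_uids = unique(selection_uids))),
            class = "har_ensemble")
}

#' @export
print.har_ensemble <- function(x, ...) {
  models <- c(if (!is.null(x$scnn)) "stacked CNN", if (!is.null(x$rf)) "random forest")
  cat(sprintf("<har_ensemble> target=%s | models: %s | classes: %s\n",
              x$target, paste(models, collapse = " + "),
              paste(x$classes, collapse = ", ")))
  if (!is.null(x$rf)) {
    cat(sprintf("  forest features: %d%s\n", length(x$rf_features),
                if (!is.null(x$selection)) sprintf(" (saturation k = %d)", x$selection$k)
                else ""))
  }
  invisible(x)
}

#' @export
summary.har_ensemble <- function(object, ...) {
  print(object)
  if (!is.null(object$scnn)) print(object$scnn)
  if (!is.null(object$rf)) print(object$rf)
  invisible(object)
}

#' Per-model and fused class probabilities for new segments
#'
#' @param object A fitted [har_fit()] ensemble.
#' @param newdata A `har_segmentset`.
#' @param type `"class"` (fused labels), `"prob"` (fused, weight-normalised
#'   probabilities) or `"all"` (list of per-model matrices + fused labels).
#' @param ... Unused.
#' @export
predict.har_ensemble <- function(object, newdata, type = c("class", "prob", "all"), ...) {
  type <- match.arg(type)
  probs <- list()
  w <- numeric(0)
  if (!is.null(object$scnn)) {
    probs$scnn <- predict(object$scnn, newdata, type = "prob")
    w <- c(w, unname(object$weights["scnn"]))
  }
  if (!is.null(object$rf)) {
    tab <- build_feature_table(newdata, filter = object$config$filter)
    probs$rf <- predict(object$rf, tab[, object$rf_features, drop = FALSE], type = "prob")
    w <- c(w, unname(object$weights["rf"]))
  }
  fused <- fuse(unname(probs), w)
  if (type == "class") return(fused)
  if (type == "prob") {
    S <- attr(fused, "scores") / sum(w)
    return(S)
  }
  list(per_model = probs, fused = fused)
}
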