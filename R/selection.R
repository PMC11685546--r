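#' Drop highly correlated features
#'
#' Computes pairwise Pearson correlations of the feature columns and greedily
#' scans upper-triangle pairs in canonical column order; for every pair with
#' `|r| > threshold` in which both members are still present, the later column
#' is dropped. Surviving pairwise `|r|` never exceeds the threshold.
#' Zero-variance columns correlate with nothing, are retained, and are
#' flagged in the log.
#'
#' @param table Feature table from [build_feature_table()] (>= 2 rows).
#' @param threshold Absolute correlation above which the later feature is
#'   dropped (default 0.9).
#' @return The pruned table; attribute `"prune_log"` records each drop as
#'   `(kept, dropped, r)`, attribute `"constant_features"` lists flagged
#'   zero-variance columns.
#' @export
correlation_prune <- function(table, threshold = 0.9) {
  check(threshold > 0 && threshold <= 1, "correlation_prune: threshold must be in (0, 1]")
  check(nrow(table) >= 2, "correlation_prune: need at least 2 rows")
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  constant <- feats[apply(X, 2, stats::sd) == 0]
  r <- suppressWarnings(stats::cor(X))
  r[!is.finite(r)] <- 0  # zero-variance columns: correlated with nothing
  alive <- rep(TRUE, length(feats))
  log <- list()
  for (i in seq_len(length(feats) - 1)) {
    if (!alive[i]) next
    for (j in (i + 1):length(feats)) {
      if (alive[j] && abs(r[i, j]) > threshold) {
        alive[j] <- FALSE
        log[[length(log) + 1]] <- data.frame(kept = feats[i], dropped = feats[j],
                                             r = r[i, j])
      }
    }
  }
  out <- table[, c(feats[alive], intersect(c("activity_id", "user_id", "segment_uid"),
                                           names(table))), drop = FALSE]
  attr(out, "prune_log") <- if (length(log)) do.call(rbind, log) else
    data.frame(kept = character(), dropped = character(), r = numeric())
  attr(out, "constant_features") <- constant
  out
}

#' Rank features by random-forest impurity importance
#'
#' Fits a [rf_fit()] forest on the (pruned) table and orders the features by
#' mean decrease in impurity, descending (ties broken by canonical column
#' order). Rows are sorted by `segment_uid` before fitting so the ranking is
#' invariant to row permutations.
#'
#' @param table Feature table (typically after [correlation_prune()]).
#' @param target `"activity"` or `"user"`.
#' @param forest_seed Seed for the ranking forest.
#' @param ntree Trees in the ranking forest.
#' @return An object of class `har_ranked`: ordered `names`, matching
#'   `scores` (non-negative, unit sum), and the inherited prune log.
#' @export
importance_rank <- function(table, target = c("activity", "user"),
                            forest_seed = 1, ntree = 500) {
  target <- match.arg(target)
  y <- table[[if (target == "activity") "activity_id" else "user_id"]]
  check(length(unique(y)) >= 2, "importance_rank: target has a single class")
  if (!is.null(table$segment_uid)) {
    table <- table[order(table$segment_uid), , drop = FALSE]
    y <- table[[if (target == "activity") "activity_id" else "user_id"]]
  }
  feats <- feature_columns(table)
  fit <- rf_fit(as.matrix(table[, feats, drop = FALSE]), y,
                ntree = ntree, seed = forest_seed)
  imp <- rf_importance(fit)
  ord <- order(-imp, seq_along(imp))  # stable: canonical order breaks ties
  structure(list(names = feats[ord], scores = unname(imp[ord]),
                 prune_log = attr(table, "prune_log")),
            class = "har_ranked")
}

#' @export
print.har_ranked <- function(x, ...) {
  cat(sprintf("<har_ranked> %d features; top 5: %s\n", length(x$names),
              paste(sprintf("%s (%.3f)", utils::head(x$names, 5),
                            utils::head(x$scores, 5)), collapse = ", ")))
  invisible(x)
}

# cross-validated random-forest accuracy used by the saturation curve:
# leave-one-user-out for activity recognition, stratified k-fold for user
# identification (a user cannot be held out of their own identification)
rf_cv_accuracy <- function(table, feats, target, seed = 1, ntree = 200, k = 5) {
  y <- table[[if (target == "activity") "activity_id" else "user_id"]]
  classes <- sort(unique(y))
  X <- as.matrix(table[, feats, drop = FALSE])
  folds <- if (target == "activity") {
    split(seq_len(nrow(table)), table$user_id)
  } else {
    with_seed(derive_seed(seed, "cvfolds"), {
      f <- rep(NA_integer_, nrow(table))
      for (cl in classes) {
        members <- sample(which(y == cl))
        f[members] <- rep_len(seq_len(k), length(members))
      }
      split(seq_len(nrow(table)), f)
    })
  }
  correct <- 0
  for (te in folds) {
    tr <- setdiff(seq_len(nrow(table)), te)
    if (length(unique(y[tr])) < 2) next
    fit <- rf_fit(X[tr, , drop = FALSE], factor(y[tr], levels = classes),
                  ntree = ntree, seed = derive_seed(seed, "cvfit", te[1]))
    pred <- predict(fit, X[te, , drop = FALSE], type = "class")
    correct <- correct + sum(as.character(pred) == y[te])
  }
  correct / nrow(table)
}

#' Select the feature count at the accuracy saturation point
#'
#' Evaluates cross-validated accuracy using the top-k ranked features over a
#' grid of k, and returns the smallest k whose accuracy is within `epsilon`
#' of the curve maximum (the point where the accuracy-vs-features curve
#' saturates). The full curve is returned for plotting.
#'
#' @param ranked A [importance_rank()] result.
#' @param table The feature table the ranking came from.
#' @param target `"activity"` or `"user"`.
#' @param epsilon Accuracy tolerance below the curve maximum (default 0.005).
#' @param k_grid Integer grid of feature counts; default every integer up to
#'   60 then strides of 5 up to the total.
#' @param evaluator Optional `function(feature_names) -> accuracy` overriding
#'   the built-in cross-validated random-forest evaluator.
#' @param seed,ntree Settings for the built-in evaluator.
#' @return Object of class `har_selection`: `selected` names, `k`, and the
#'   `curve` data frame (`k`, `accuracy`).
#' @export
saturation_select <- function(ranked, table, target = c("activity", "user"),
                              epsilon = 0.005, k_grid = NULL, evaluator = NULL,
                              seed = 1, ntree = 200) {
  target <- match.arg(target)
  check(inherits(ranked, "har_ranked") && length(ranked$names) > 0,
        "saturation_select: ranked features must be non-empty")
  p <- length(ranked$names)
  if (is.null(k_grid)) {
    k_grid <- unique(c(seq_len(min(60, p)),
                       if (p > 60) seq(65, p, by = 5), p))
  }
  k_grid <- sort(unique(pmin(k_grid, p)))
  if (is.null(evaluator)) {
    evaluator <- function(feats) rf_cv_accuracy(table, feats, target,
                                                seed = seed, ntree = ntree)
  }
  acc <- vapply(k_grid, function(k) evaluator(ranked$names[seq_len(k)]), numeric(1))
  k_sel <- k_grid[which(acc >= max(acc) - epsilon)[1]]
  structure(list(selected = ranked$names[seq_len(k_sel)], k = k_sel,
                 curve = data.frame(k = k_grid, accuracy = acc)),
            class = "har_selection")
}

#' @export
print.har_selection <- function(x, ...) {
  cat(sprintf("<har_selection> k = %d of %d; curve max accuracy %.3f\n",
              x$k, max(x$curve$k), max(x$curve$accuracy)))
  invisible(x)
}

#' @export
plot.har_selection <- function(x, ...) {
  graphics::plot(x$curve$k, x$curve$accuracy, type = "b", pch = 16,
                 xlab = "number of top-ranked features",
                 ylab = "cross-validated accuracy", ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}
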