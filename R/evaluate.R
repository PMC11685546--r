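#' Leave-one-subject-out cross-validation of the ensemble
#'
#' One fold per user: the full training pipeline — augmentation, feature
#' extraction, feature selection, both models — is fitted on the remaining
#' users only and evaluated on the held-out user, so no held-out segment ever
#' enters an augmentation pool, a selection fit or a training batch (the
#' per-fold `provenance` records the uid sets and can be audited).
#'
#' Pooled accuracy is the confusion-matrix trace over the total count;
#' precision, recall and F1 are fold means. For nurse identification the
#' held-out subject's identity cannot be predicted by construction, so
#' `target = "user"` must be evaluated with [stratified_cv()] instead.
#'
#' @param set A `har_segmentset` with at least 2 users.
#' @param target Only `"activity"` is meaningful here.
#' @param config A [har_config()].
#' @return A `har_eval` report with per-fold accuracies, summed confusion
#'   matrix, fold->user map and provenance.
#' @export
losocv <- function(set, target = "activity", config = har_config()) {
  check(target == "activity",
        "losocv: a held-out user's identity cannot be predicted; use stratified_cv() for target = 'user'")
  us <- users(set)
  folds <- sort(unique(us))
  check(length(folds) >= 2, "losocv: need at least 2 users")
  classes <- sort(unique(activities(set)))
  y_true <- character(0); y_pred <- character(0)
  fold_reports <- list(); provenance <- list()
  for (u in folds) {
    test_set <- set[us == u]
    train_set <- set[us != u]
    if (length(unique(activities(train_set))) < 2) {
      warning(sprintf("fold %s: training users cover < 2 classes; fold skipped", u))
      next
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "fold", u)
    fit <- har_fit(train_set, target = target, config = cfg)
    pred <- as.character(predict(fit, test_set, type = "class"))
    truth <- activities(test_set)
    y_true <- c(y_true, truth)
    y_pred <- c(y_pred, pred)
    fold_reports[[u]] <- compute_metrics(truth, pred, classes = classes)
    provenance[[u]] <- c(fit$provenance,
                         list(test_uids = segment_uids(test_set)))
  }
  check(length(fold_reports) >= 1, "losocv: no evaluable folds")
  agg <- compute_metrics(y_true, y_pred, classes = classes)
  agg$precision <- mean(vapply(fold_reports, `[[`, numeric(1), "precision"))
  agg$recall <- mean(vapply(fold_reports, `[[`, numeric(1), "recall"))
  agg$f1 <- mean(vapply(fold_reports, `[[`, numeric(1), "f1"))
  agg$fold_accuracy <- vapply(fold_reports, `[[`, numeric(1), "accuracy")
  agg$folds <- fold_reports
  agg$provenance <- provenance
  agg$protocol <- "losocv"
  agg
}

#' Stratified k-fold evaluation (used for nurse identification)
#'
#' Folds are stratified on the target label so every fold sees all classes;
#' as in [losocv()], augmentation, selection and model fitting happen inside
#' each training fold only.
#'
#' @param set A `har_segmentset`.
#' @param target `"user"` or `"activity"`.
#' @param k Number of folds.
#' @param config A [har_config()].
#' @return A `har_eval` report (same structure as [losocv()]).
#' @export
stratified_cv <- function(set, target = c("user", "activity"), k = 5,
                          config = har_config()) {
  target <- match.arg(target)
  labs <- if (target == "user") users(set) else activities(set)
  classes <- sort(unique(labs))
  check(length(classes) >= 2, "stratified_cv: need at least 2 classes")
  fold_of <- with_seed(derive_seed(config$seed, "strata"), {
    f <- integer(length(set))
    for (cl in classes) {
      members <- sample(which(labs == cl))
      f[members] <- rep_len(seq_len(k), length(members))
    }
    f
  })
  y_true <- character(0); y_pred <- character(0)
  fold_reports <- list(); provenance <- list()
  for (fold in seq_len(k)) {
    te <- fold_of == fold
    if (!any(te) || length(unique(labs[!te])) < 2) next
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "fold", fold)
    fit <- har_fit(set[!te], target = target, config = cfg)
    pred <- as.character(predict(fit, set[te], type = "class"))
    truth <- labs[te]
    y_true <- c(y_true, truth)
    y_pred <- c(y_pred, pred)
    fold_reports[[as.character(fold)]] <- compute_metrics(truth, pred, classes = classes)
    provenance[[as.character(fold)]] <- c(fit$provenance,
                                          list(test_uids = segment_uids(set[te])))
  }
  check(length(fold_reports) >= 1, "stratified_cv: no evaluable folds")
  agg <- compute_metrics(y_true, y_pred, classes = classes)
  agg$precision <- mean(vapply(fold_reports, `[[`, numeric(1), "precision"))
  agg$recall <- mean(vapply(fold_reports, `[[`, numeric(1), "recall"))
  agg$f1 <- mean(vapply(fold_reports, `[[`, numeric(1), "f1"))
  agg$fold_accuracy <- vapply(fold_reports, `[[`, numeric(1), "accuracy")
  agg$folds <- fold_reports
  agg$provenance <- provenance
  agg$protocol <- sprintf("stratified %d-fold", k)
  agg
}
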