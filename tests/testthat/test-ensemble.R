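test_that("weighted fusion reproduces the worked arithmetic", {
  p1 <- matrix(c(0.6, 0.4), 1, dimnames = list(NULL, c("A", "B")))
  p2 <- matrix(c(0.0, 1.0), 1, dimnames = list(NULL, c("A", "B")))
  out <- fuse(list(p1, p2), weights = c(2, 1))
  expect_equal(as.character(out), "B")  # A: 1.2 vs B: 1.8
  expect_equal(unname(attr(out, "scores")[1, ]), c(1.2, 1.8))
  # zero weight on the second model reduces to the first model's argmax
  expect_equal(as.character(fuse(list(p1, p2), c(1, 0))), "A")
})

test_that("fusion agrees with unanimous models and validates congruence", {
  set.seed(3)
  raw <- matrix(runif(40), 10)
  p1 <- raw / rowSums(raw)
  colnames(p1) <- paste0("C", 1:4)
  p2 <- p1^2 / rowSums(p1^2)
  colnames(p2) <- paste0("C", 1:4)
  a1 <- max.col(p1, ties.method = "first")
  for (w in list(c(1, 1), c(2, 1), c(0.3, 5))) {
    if (all(max.col(p2, ties.method = "first") == a1)) {
      expect_equal(as.integer(fuse(list(p1, p2), w)), a1)
    }
  }
  # equal weights are invariant to model ordering
  expect_equal(attr(fuse(list(p1, p2), c(1, 1)), "scores"),
               attr(fuse(list(p2, p1), c(1, 1)), "scores"))
  bad <- p2[, c(2, 1, 3, 4)]
  expect_error(fuse(list(p1, bad), c(1, 1)), "class order")
  expect_error(fuse(list(p1, p2[1:5, ]), c(1, 1)), "shape")
  expect_error(fuse(list(p1, p2), c(0, 0)), "positive")
})

test_that("metrics match hand arithmetic and the confusion matrix adds up", {
  y <- c("A", "A", "B", "B")
  m <- compute_metrics(y, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  # 2-class counts TP=3, FP=1, FN=1, TN=5 for the positive class
  y_true <- c(rep("pos", 4), rep("neg", 6))
  y_pred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  m2 <- compute_metrics(y_true, y_pred)
  expect_equal(m2$per_class$precision[m2$per_class$class == "pos"], 0.75)
  expect_equal(m2$per_class$recall[m2$per_class$class == "pos"], 0.75)
  expect_equal(sum(m2$confusion), 10)
  expect_equal(m2$accuracy, sum(diag(m2$confusion)) / 10)
  # constant predictions on balanced 2-class data score 50%
  m3 <- compute_metrics(rep(c("A", "B"), 5), rep("A", 10))
  expect_equal(m3$accuracy, 0.5)
  expect_error(compute_metrics(character(0), character(0)), "empty")
})

test_that("the fitted ensemble predicts with normalised fused probabilities", {
  set <- generate_dataset(generator_config(n_users = 2, n_activities = 2,
                                           segments_per_class = 8,
                                           segment_length_range = c(60, 80), seed = 14))
  cfg <- har_config(scnn = scnn_config(epochs = 10, patience = 10),
                    rf = list(ntree = 50), select = "none", seed = 2)
  fit <- har_fit(set, "activity", cfg)
  pr <- predict(fit, set, type = "prob")
  expect_equal(dim(pr), c(16, 2))
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-6)
  all_out <- predict(fit, set, type = "all")
  expect_named(all_out$per_model, c("scnn", "rf"))
  fused_by_hand <- fuse(unname(all_out$per_model), c(2, 1))
  expect_identical(as.character(all_out$fused), as.character(fused_by_hand))
})

test_that("LOSOCV builds one fold per user and tests each segment once", {
  set <- generate_dataset(generator_config(n_users = 3, n_activities = 3,
                                           segments_per_class = 6, seed = 4))
  cfg <- har_config(scnn = NULL, rf = list(ntree = 60), select = "none", seed = 3)
  rep <- losocv(set, "activity", cfg)
  expect_named(rep$fold_accuracy, c("U1", "U2", "U3"))
  expect_equal(rep$n, length(set))
  expect_equal(sum(rep$confusion), length(set))
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / length(set))
  expect_error(losocv(set, "user", cfg), "stratified_cv")
})

test_that("LOSOCV never leaks held-out segments into any training stage", {
  set <- generate_dataset(generator_config(n_users = 3, n_activities = 2,
                                           segments_per_class = c(8, 3), seed = 9))
  cfg <- har_config(augment = augmentation_plan(A = 8, types = "tw", seed = 5),
                    scnn = NULL, rf = list(ntree = 60), select = "prune", seed = 3)
  rep <- losocv(set, "activity", cfg)
  for (u in names(rep$provenance)) {
    pv <- rep$provenance[[u]]
    expect_length(intersect(pv$test_uids, pv$train_uids), 0)
    expect_length(intersect(pv$test_uids, pv$aug_parent_uids), 0)
    expect_length(intersect(pv$test_uids, pv$selection_uids), 0)
    expect_true(all(pv$aug_parent_uids %in% pv$original_uids))
    expect_true(all(pv$selection_uids %in% pv$train_uids))
    # every fold's training pool is exactly the other users' segments + augments
    expect_true(all(users(set)[match(pv$original_uids, segment_uids(set))] != u))
  }
})

test_that("stratified folds evaluate nurse identification on all users", {
  set <- generate_dataset(generator_config(n_users = 3, n_activities = 2,
                                           segments_per_class = 9, seed = 10))
  cfg <- har_config(scnn = NULL, rf = list(ntree = 60), select = "none", seed = 6)
  rep <- stratified_cv(set, "user", k = 3, config = cfg)
  expect_equal(rep$n, length(set))
  expect_setequal(rownames(rep$confusion), c("U1", "U2", "U3"))
  expect_gt(rep$accuracy, 1 / 3)
})
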