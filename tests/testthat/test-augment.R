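test_that("jitter adds seeded Gaussian noise and degenerates to identity", {
  seg <- make_seg(3400, seed = 1)
  expect_equal(jitter(seg, mu = 0, sigma = 0)$xyz, seg$xyz)
  out <- jitter(seg, mu = 0.01, sigma = 0.05, seed = 9)
  n_cells <- length(seg$xyz)
  expect_lt(abs(mean(out$xyz - seg$xyz) - 0.01), 3 * 0.05 / sqrt(n_cells))
  expect_identical(jitter(seg, mu = 0.01, sigma = 0.05, seed = 9)$xyz, out$xyz)
  expect_equal(out$source_id, "jitter")
  expect_equal(out$parent_uid, seg$uid)
})

test_that("scaling is multiplicative noise with exact degenerate cases", {
  seg <- make_seg(50, seed = 2)
  expect_equal(scaling(seg, mu = 1, sigma = 0)$xyz, seg$xyz)
  expect_equal(scaling(seg, mu = 2, sigma = 0)$xyz, 2 * seg$xyz)
  zero <- segment(matrix(0, 10, 3), 60, "A1", "U1")
  expect_equal(scaling(zero, mu = 3, sigma = 1, seed = 1)$xyz, zero$xyz)
})

test_that("random curves interpolate their knots and match an independent spline", {
  expect_equal(random_curve(40, phi = 4, mu = 2, sigma = 0), rep(2, 40))
  # phi = 4, m = 101: the 6 knots land on integer positions 0,20,...,100
  kn <- with_seed(77, stats::rnorm(6, 1, 0.2))
  curve <- random_curve(101, phi = 4, mu = 1, sigma = 0.2, seed = 77)
  expect_lt(max(abs(curve[c(0, 20, 40, 60, 80, 100) + 1] - kn)), 1e-9)
  # full pointwise agreement with the hand-written natural-spline oracle
  kn2 <- with_seed(13, stats::rnorm(6, 1, 0.2))
  oracle <- natural_spline_oracle(seq(0, 99, length.out = 6), kn2, 0:99)
  expect_lt(max(abs(random_curve(100, phi = 4, seed = 13) - oracle)), 1e-8)
})

test_that("magnitude warping multiplies all axes by one shared curve", {
  seg <- make_seg(90, seed = 3)
  expect_equal(magnitude_warp(seg, mu = 1, sigma = 0)$xyz, seg$xyz)
  out <- magnitude_warp(seg, seed = 4)
  curve <- random_curve(90, seed = 4)
  ratio <- out$xyz / seg$xyz
  expect_lt(max(abs(ratio - curve)), 1e-9)  # same curve on every axis
})

test_that("time warping with a constant curve is the identity", {
  seg <- make_seg(100, seed = 5)
  out <- time_warp(seg, sigma = 0, seed = 1)
  expect_lt(max(abs(out$xyz - seg$xyz)), 1e-9)
  expect_equal(nrow(out$xyz), nrow(seg$xyz))
})

test_that("time warping pins endpoints and preserves monotone ramps", {
  for (s in 1:100) {
    seg <- segment(cbind(ax = seq(0, 5, length.out = 80),
                         ay = seq(2, -3, length.out = 80), az = 1), 60, "A1", "U1")
    out <- time_warp(seg, seed = s)
    expect_equal(nrow(out$xyz), 80)
    expect_lt(abs(out$xyz[1, 1] - seg$xyz[1, 1]), 1e-9)
    expect_lt(abs(out$xyz[80, 1] - seg$xyz[80, 1]), 1e-9)
    expect_true(all(diff(out$xyz[, 1]) >= -1e-12))  # increasing stays increasing
    expect_true(all(diff(out$xyz[, 2]) <= 1e-12))
  }
})

test_that("the axis-angle rotation matrix matches the worked case", {
  Q <- rotation_matrix(c(0, 0, 1), pi / 2)
  expect_equal(Q, matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(as.numeric(c(1, 0, 0) %*% Q), c(0, -1, 0), tolerance = 1e-12)
  expect_equal(rotation_matrix(c(0, 1, 0), 0), diag(3))
})

test_that("rotation preserves per-sample magnitude on random draws", {
  for (s in 1:20) {
    seg <- make_seg(60, seed = s)
    out <- rotation(seg, seed = s + 100)
    expect_lt(max(abs(compute_magnitude(out) - compute_magnitude(seg))), 1e-9)
  }
})

test_that("every operator preserves labels, length and is seed-deterministic", {
  seg <- make_seg(70, seed = 6, activity = "A3", user = "U2")
  ops <- list(function(s) jitter(s, seed = 1), function(s) scaling(s, seed = 1),
              function(s) magnitude_warp(s, seed = 1),
              function(s) time_warp(s, seed = 1), function(s) rotation(s, seed = 1))
  for (op in ops) {
    out <- op(seg)
    expect_equal(out$activity_id, "A3")
    expect_equal(out$user_id, "U2")
    expect_equal(nrow(out$xyz), 70)
    expect_identical(op(seg)$xyz, out$xyz)
  }
})

test_that("balance_augment fills every class to exactly A segments", {
  segs <- c(lapply(1:5, function(i) make_seg(60, seed = i, activity = "A", user = "U1")),
            lapply(6:7, function(i) make_seg(60, seed = i, activity = "B", user = "U2")))
  set <- segment_set(segs)
  out <- balance_augment(set, augmentation_plan(A = 5, types = "tw", seed = 1))
  expect_equal(class_counts(out), c(A = 5L, B = 5L))
  aug <- out$segments[vapply(out$segments, function(s) s$source_id != "original", logical(1))]
  expect_equal(length(aug), 3)
  expect_true(all(vapply(aug, `[[`, character(1), "source_id") == "tw"))
  # A equal to the current counts is a no-op
  same <- balance_augment(set[1:5], augmentation_plan(A = 5, types = "jitter"))
  expect_identical(same$segments, set[1:5]$segments)
  # degenerate jitter produces exact duplicates of the cycled originals
  dup <- balance_augment(set, augmentation_plan(A = 7, types = "jitter",
                                                params = list(jitter = list(sigma = 0))))
  b_orig <- set$segments[6:7]
  b_aug <- dup$segments[vapply(dup$segments, function(s) {
    s$source_id == "jitter" && s$parent_uid %in% c(b_orig[[1]]$uid, b_orig[[2]]$uid)
  }, logical(1))]
  expect_equal(length(b_aug), 5)  # cycled b1, b2, b1, b2, b1
  expect_identical(b_aug[[1]]$xyz, b_orig[[1]]$xyz)
  expect_identical(b_aug[[2]]$xyz, b_orig[[2]]$xyz)
  expect_identical(b_aug[[3]]$xyz, b_orig[[1]]$xyz)
  # A below the maximum class count is rejected
  expect_error(balance_augment(set, augmentation_plan(A = 4, types = "tw")), "below")
})

test_that("operator pairs compose left to right", {
  seg <- make_seg(80, seed = 9)
  plan <- augmentation_plan(A = 2, types = "mw+tw", seed = 3)
  out <- balance_augment(segment_set(list(seg)), plan)
  expect_equal(length(out), 2)
  expect_equal(out$segments[[2]]$source_id, "mw+tw")
  # reproduce by hand with the same derived seeds
  manual <- carehar:::apply_augmentation(seg, "mw+tw", list(),
                                         seed = derive_seed(3, "A1", 0))
  expect_identical(out$segments[[2]]$xyz, manual$xyz)
})

test_that("balanced output is deterministic in the plan seed", {
  set <- segment_set(lapply(1:3, function(i) make_seg(60, seed = i,
                                                      activity = c("A", "B")[1 + i %% 2])))
  plan <- augmentation_plan(A = 6, types = c("jitter", "tw"), seed = 11)
  a <- balance_augment(set, plan)
  b <- balance_augment(set, plan)
  expect_identical(a, b)
})
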