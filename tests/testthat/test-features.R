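test_that("magnitude is the per-sample L2 norm and rotation-invariant", {
  expect_equal(compute_magnitude(matrix(c(3, 4, 12), 1)), 13)
  expect_equal(compute_magnitude(matrix(0, 1, 3)), 0)
  seg <- make_seg(50, seed = 1)
  rot <- rotation(seg, seed = 2)
  expect_lt(max(abs(compute_magnitude(rot) - compute_magnitude(seg))), 1e-9)
})

test_that("orientation angles follow the arctan construction with conventions", {
  a <- compute_angles(matrix(c(0, 0, 1), 1))
  expect_equal(unname(a[1, "angle_z"]), pi / 2)
  b <- compute_angles(matrix(c(1, 1, sqrt(2)), 1))
  expect_equal(unname(b[1, "angle_z"]), pi / 4)
  cc <- compute_angles(matrix(c(1, 0, 0), 1))
  expect_equal(unname(cc[1, "angle_z"]), 0)
  expect_equal(unname(cc[1, "angle_x"]), pi / 2)
  z <- compute_angles(matrix(0, 1, 3))
  expect_equal(unname(z[1, ]), c(0, 0, 0))  # all-zero sample maps to 0
  r <- compute_angles(make_seg(30, seed = 2))
  expect_true(all(r >= -pi / 2 & r <= pi / 2))
})

test_that("trapezoidal integration matches closed forms", {
  expect_equal(integrate_series(rep(1, 5), dt = 1), 0:4)
  expect_equal(integrate_series(rep(0, 5), dt = 1), rep(0, 5))
  expect_equal(integrate_series(rep(0, 5), dt = 1, order = 2), rep(0, 5))
  # constant acceleration 2, dt = 0.5: displacement at index n is a t^2 / 2
  n <- 0:9
  disp <- integrate_series(rep(2, 10), dt = 0.5, order = 2)
  expect_lt(max(abs(disp - n^2 * 0.25)), 1e-9)
  expect_error(integrate_series(1:3, dt = 0), "dt")
})

test_that("the intermediate feature set has exactly 13 canonical columns", {
  seg <- make_seg(64, seed = 3)
  ifs <- compute_ifs(seg)
  expect_equal(ncol(ifs), 13)
  expect_equal(nrow(ifs), 64)
  expect_identical(colnames(ifs), ifs_columns())
  zero <- compute_ifs(segment(matrix(0, 20, 3), 60, "A1", "U1"))
  expect_true(all(zero == 0))
})

test_that("msum matches the literal pairing rule and the brute-force oracle", {
  expect_equal(msum(1:10), 0)                 # monotone: no interior extrema
  expect_equal(msum(rep(2, 8)), 0)
  x <- c(0, 2, 0, 3, 0, 4, 0, 5, 0)
  expect_equal(msum(x), msum_oracle(x))
  expect_equal(msum_oracle(x), 3.5)           # hand-checked: (2+4+3+5)/4
  expect_equal(msum(x + 17.3), msum(x))       # shift invariance
  set.seed(42)
  for (i in 1:200) {
    y <- rnorm(sample(50:500, 1))
    expect_identical(msum(y), msum_oracle(y))
  }
})

test_that("the final feature set holds 117 uniquely named statistics", {
  seg <- make_seg(70, seed = 4)
  ffs <- compute_ffs(compute_ifs(seg))
  expect_length(ffs, 117)
  expect_equal(anyDuplicated(names(ffs)), 0)
  expect_true(all(paste0("magnitude_", ffs_stats()) %in% names(ffs)))
  expect_equal(unname(ffs["ax_var"]), unname(ffs["ax_sd"]^2), tolerance = 1e-9)
})

test_that("statistics of a constant column are defined, not errors", {
  ifs <- compute_ifs(segment(matrix(2, 30, 3), 60, "A1", "U1"))
  ifs[, ] <- 0
  ifs[, "ax"] <- 5
  ffs <- compute_ffs(ifs)
  expect_equal(unname(ffs[paste0("ax_", c("sd", "avg", "max", "min", "var",
                                          "mad", "msum", "energy", "iqr"))]),
               c(0, 5, 5, 5, 0, 0, 0, 25, 0))
})

test_that("mad, iqr and energy follow their stated definitions", {
  x <- c(1, 2, 3, 4)
  ifs <- matrix(rep(x, 13), ncol = 13, dimnames = list(NULL, ifs_columns()))
  ffs <- compute_ffs(ifs)
  expect_equal(unname(ffs["ax_mad"]), 1)       # median(|x - 2.5|) = 1
  expect_equal(unname(ffs["ax_iqr"]), 1.5)     # type-7 quantiles: 3.25 - 1.75
  expect_equal(unname(ffs["ax_energy"]), 7.5)  # mean of squares
})

test_that("acceleration statistics are scale-equivariant", {
  seg <- make_seg(80, seed = 5)
  s <- 2.5
  scl <- seg; scl$xyz <- s * scl$xyz
  f0 <- compute_ffs(compute_ifs(seg))
  f1 <- compute_ffs(compute_ifs(scl))
  for (col in c("ax", "ay", "az")) {
    for (st in c("sd", "avg", "max", "min", "mad", "msum", "iqr")) {
      expect_equal(unname(f1[paste0(col, "_", st)]),
                   s * unname(f0[paste0(col, "_", st)]), tolerance = 1e-9)
    }
    expect_equal(unname(f1[paste0(col, "_var")]),
                 s^2 * unname(f0[paste0(col, "_var")]), tolerance = 1e-9)
    expect_equal(unname(f1[paste0(col, "_energy")]),
                 s^2 * unname(f0[paste0(col, "_energy")]), tolerance = 1e-9)
  }
})

test_that("all nine magnitude statistics are rotation-invariant", {
  seg <- make_seg(90, seed = 6)
  rot <- rotation(seg, seed = 7)
  f0 <- compute_ffs(compute_ifs(seg))
  f1 <- compute_ffs(compute_ifs(rot))
  idx <- paste0("magnitude_", ffs_stats())
  expect_lt(max(abs(f1[idx] - f0[idx])), 1e-9)
})

test_that("the feature table stacks one labelled row per segment, bitwise reproducibly", {
  set <- generate_dataset(generator_config(n_users = 2, n_activities = 2,
                                           segments_per_class = 10, seed = 12))
  tab <- build_feature_table(set)
  expect_equal(nrow(tab), 20)
  expect_length(feature_columns(tab), 117)
  expect_false(anyNA(tab))
  expect_identical(tab$activity_id, activities(set))
  expect_identical(build_feature_table(set), tab)
})
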