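test_that("ds2 CSVs parse ISO and numeric timestamps into canonical seconds", {
  p <- write_ds2_csv(data.frame(
    timestamp = c("2021-01-01T00:00:00", "2021-01-01T00:00:01", "2021-01-01T00:00:02"),
    ax = 1:3 / 10, ay = 0, az = 1))
  s <- read_sensor_csv(p, "ds2")
  expect_equal(nrow(s), 3)
  expect_true(is.numeric(s$timestamp))
  expect_equal(diff(s$timestamp), c(1, 1))

  p2 <- write_ds2_csv(data.frame(timestamp = c(5, 1, 3), ax = 1:3, ay = 0, az = 0))
  expect_equal(read_sensor_csv(p2, "ds2")$timestamp, c(5, 1, 3))
})

test_that("ds1 rows map onto segment id and elapsed time fields", {
  p <- write_ds2_csv(data.frame(segment_id = 7, elapsed_time = 0.25,
                                ax = 0.1, ay = 0.2, az = 0.3))
  s <- read_sensor_csv(p, "ds1")
  expect_equal(s$segment_id, 7L)
  expect_equal(s$elapsed_time, 0.25)
  expect_equal(unlist(s[, c("ax", "ay", "az")], use.names = FALSE), c(0.1, 0.2, 0.3))
})

test_that("format errors name the missing column and bad timestamp rows", {
  p <- write_ds2_csv(data.frame(timestamp = 1, ax = 1, ay = 1))
  expect_error(read_sensor_csv(p, "ds2"), "az")
  p2 <- write_ds2_csv(data.frame(timestamp = c("2021-01-01T00:00:00", "not-a-time"),
                                 ax = 1, ay = 1, az = 1))
  expect_error(read_sensor_csv(p2, "ds2"), "row")
})

test_that("normalize_and_sort is stable, permutation-invariant and idempotent", {
  df <- data.frame(timestamp = c(3, 1, 2), ax = c(30, 10, 20), ay = 0, az = 0)
  out <- normalize_and_sort(df, "ds2")
  expect_equal(out$timestamp, c(1, 2, 3))
  expect_equal(out$ax, c(10, 20, 30))
  # duplicate timestamps keep original relative order
  df2 <- data.frame(timestamp = c(2, 1, 1), ax = c(9, 5, 6), ay = 0, az = 0)
  expect_equal(normalize_and_sort(df2, "ds2")$ax, c(5, 6, 9))
  # idempotent, and a shuffled copy sorts to the same table
  expect_identical(normalize_and_sort(out, "ds2"), out)
  shuf <- df[c(2, 3, 1), ]
  expect_equal(normalize_and_sort(shuf, "ds2")$ax, out$ax)
  expect_identical(normalize_and_sort(df[0, ], "ds2"), df[0, ])
})

test_that("mean imputation fills per-column means and rejects empty columns", {
  df <- data.frame(timestamp = 1:3, ax = c(1, NA, 3), ay = c(NA, 2, 4), az = 1)
  out <- impute_missing(df)
  expect_equal(out$ax, c(1, 2, 3))
  expect_equal(out$ay, c(3, 2, 4))
  clean <- data.frame(timestamp = 1:2, ax = 1:2, ay = 1:2, az = 1:2)
  expect_identical(impute_missing(clean), clean)
  expect_error(impute_missing(data.frame(timestamp = 1:2, ax = c(NA_real_, NA),
                                         ay = 1, az = 1)), "ax")
})

test_that("ds1 label merge joins on segment id and partitions labelled samples", {
  samples <- data.frame(segment_id = rep(c(1L, 2L, 9L), c(10, 6, 4)),
                        elapsed_time = c(1:10, 1:6, 1:4) / 4,
                        ax = rnorm(20), ay = rnorm(20), az = rnorm(20))
  labels <- data.frame(user_id = c("A", "B"), segment_id = c(1L, 2L),
                       activity_id = c("Oral Care", "Walk"))
  set <- merge_labels(samples, labels, "ds1", fs = 4)
  expect_s3_class(set, "har_segmentset")
  expect_equal(length(set), 2)
  expect_equal(nrow(set$segments[[1]]$xyz), 10)
  expect_equal(set$segments[[1]]$activity_id, "Oral Care")
  expect_equal(set$segments[[1]]$user_id, "A")
  # partition invariant: segment lengths sum to the labelled-sample count
  labelled <- sum(samples$segment_id %in% labels$segment_id)
  expect_equal(sum(vapply(set$segments, function(s) nrow(s$xyz), numeric(1))), labelled)
  expect_equal(set$log$dropped_samples, 4)
})

test_that("ds2 label merge uses closed intervals and reports exclusions", {
  samples <- data.frame(timestamp = 1:10, ax = 1:10, ay = 0, az = 0)
  labels <- data.frame(user_id = "U1", activity_id = "A1",
                       start_time = 3, finish_time = 6)
  set <- merge_labels(samples, labels, "ds2", fs = 1)
  expect_equal(length(set), 1)
  expect_equal(nrow(set$segments[[1]]$xyz), 4)  # t in {3,4,5,6}
  expect_equal(set$segments[[1]]$xyz[, "ax"], 3:6)
  expect_equal(set$log$dropped_samples, 6)
})

test_that("overlapping ds2 intervals error by default and honour first-wins", {
  samples <- data.frame(timestamp = 1:10, ax = 0, ay = 0, az = 0)
  labels <- data.frame(user_id = "U1", activity_id = c("A1", "A2"),
                       start_time = c(1, 4), finish_time = c(6, 10))
  expect_error(merge_labels(samples, labels, "ds2"), "overlap")
  set <- merge_labels(samples, labels, "ds2", overlap = "first")
  expect_equal(length(set), 2)
  expect_equal(nrow(set$segments[[1]]$xyz), 6)
  expect_equal(nrow(set$segments[[2]]$xyz), 4)  # only the unclaimed 7..10
})

test_that("windowing slices long segments and handles short ones per policy", {
  long <- segment(matrix(rnorm(180 * 3), ncol = 3), 60, "A1", "U1", uid = "L")
  exact <- segment(matrix(rnorm(60 * 3), ncol = 3), 60, "A1", "U1", uid = "E")
  short <- segment(matrix(rnorm(59 * 3), ncol = 3), 60, "A1", "U1", uid = "S")
  w <- window_segments(segment_set(list(long)), 60, 60)
  expect_equal(length(w), 3)
  expect_true(all(vapply(w$segments, function(s) nrow(s$xyz), numeric(1)) == 60))
  # total sample count conserved when length divides the window
  expect_equal(sum(vapply(w$segments, function(s) nrow(s$xyz), numeric(1))), 180)
  w1 <- window_segments(segment_set(list(exact)), 60, 60)
  expect_equal(length(w1), 1)
  expect_equal(w1$segments[[1]]$xyz, exact$xyz)
  wd <- window_segments(segment_set(list(short)), 60, 60, short = "drop")
  expect_equal(length(wd), 0)
  expect_equal(wd$log$short_dropped, 1)
  wk <- window_segments(segment_set(list(short)), 60, 60, short = "keep")
  expect_equal(length(wk), 1)
})

test_that("the segment store round-trips values and labels bit-identically", {
  set <- generate_dataset(generator_config(n_users = 2, n_activities = 2,
                                           segments_per_class = 3, seed = 8))
  p <- tempfile(fileext = ".csv")
  write_segments(set, p)
  rt <- read_segments(p)
  expect_equal(length(rt), length(set))
  for (i in seq_along(set$segments)) {
    expect_identical(rt$segments[[i]]$xyz, set$segments[[i]]$xyz)
  }
  expect_identical(activities(rt), activities(set))
  expect_identical(users(rt), users(set))
  expect_true(file.exists(paste0(p, ".json")))
})

test_that("per-user segment imputation never crosses users", {
  s1 <- segment(cbind(ax = c(1, NA, 3), ay = 1:3, az = 1:3), 60, "A1", "U1", uid = "a")
  s2 <- segment(cbind(ax = c(100, 100, 100), ay = 1:3, az = 1:3), 60, "A1", "U2", uid = "b")
  out <- impute_segments(segment_set(list(s1, s2)))
  expect_equal(out$segments[[1]]$xyz[2, "ax"], c(ax = 2))  # mean of U1 only
})
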