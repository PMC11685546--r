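#' Configuration for the synthetic accelerometer generator
#'
#' The generator emulates per-(activity, user) tri-axial motion: each activity
#' is a two-harmonic sinusoid motif with an activity-specific base frequency
#' and per-axis amplitudes riding on a constant gravity-like offset; each user
#' wears the sensor at a fixed tilt, applied as an axis-angle rotation of the
#' whole segment; sensor noise is additive Gaussian in the device frame.
#' Within a class, the motif draw (phases, amplitude and frequency jitter,
#' segment length) is keyed by the replicate index only, so corresponding
#' segments of different users differ by rotation and noise alone.
#'
#' @param n_users,n_activities Counts (`>= 1`).
#' @param fs Sampling rate in Hz (default 60, the higher-rate armband setup).
#' @param segment_length_range `(min, max)` samples per segment.
#' @param segments_per_class Integer vector of per-activity segment counts
#'   (the imbalance vector); recycled to `n_activities`.
#' @param noise_sd Gaussian sensor-noise SD in acceleration units (default
#'   0.05 g, a realistic consumer-MEMS figure).
#' @param missing_rate Fraction of acceleration cells blanked to `NA`.
#' @param seed Integer root seed.
#' @return An object of class `har_genconfig`.
#' @export
generator_config <- function(n_users = 4, n_activities = 4, fs = 60,
                             segment_length_range = c(120, 240),
                             segments_per_class = 12,
                             noise_sd = 0.05, missing_rate = 0, seed = 1) {
  check(n_users >= 1 && n_activities >= 1, "generator_config: counts must be >= 1")
  check(missing_rate >= 0 && missing_rate < 1,
        "generator_config: missing_rate must be in [0, 1)")
  check(segment_length_range[1] <= segment_length_range[2] &&
        segment_length_range[1] >= 2,
        "generator_config: invalid segment_length_range")
  spc <- rep_len(as.integer(segments_per_class), n_activities)
  check(all(spc >= 1), "generator_config: segments_per_class must be >= 1")
  cfg <- list(n_users = as.integer(n_users), n_activities = as.integer(n_activities),
              fs = fs, segment_length_range = as.integer(segment_length_range),
              segments_per_class = spc, noise_sd = noise_sd,
              missing_rate = missing_rate, seed = as.integer(seed))
  base_freq <- 0.6 + 0.7 * (seq_len(n_activities) - 1)
  check(all(2 * base_freq < fs / 2),
        "generator_config: motif harmonic frequency %.2f Hz reaches Nyquist %.2f Hz",
        max(2 * base_freq), fs / 2)
  structure(cfg, class = "har_genconfig")
}

# deterministic activity motif parameters (frequencies Hz, per-axis amplitudes)
motif_params <- function(ia) {
  list(freq = 0.6 + 0.7 * (ia - 1),
       amp1 = 0.35 + 0.15 * sin(ia + c(1, 2, 3)),
       amp2 = (0.25 + 0.06 * ia) * c(0.6, 1, 0.8))
}

# deterministic user tilt (axis-angle); user 1 is untilted
user_tilt <- function(iu) {
  u <- c(sin(iu), cos(iu), 0.5)
  list(u = u / sqrt(sum(u^2)), theta = 0.35 * (iu - 1))
}

#' Generate a seeded, labelled synthetic segment set
#'
#' Deterministic under a fixed seed; class counts equal
#' `segments_per_class` exactly.
#'
#' @param config A [generator_config()].
#' @return A `har_segmentset` with activities `A1..` and users `U1..`.
#' @export
#' @examples
#' set <- generate_dataset(generator_config(n_users = 2, n_activities = 2,
#'                                          segments_per_class = c(4, 2)))
#' class_counts(set)
generate_dataset <- function(config) {
  check(inherits(config, "har_genconfig"), "generate_dataset: need a generator_config()")
  segs <- list()
  k <- 0L
  for (ia in seq_len(config$n_activities)) {
    mp <- motif_params(ia)
    n_class <- config$segments_per_class[ia]
    # distribute the class count over users (first users get the remainder)
    per_user <- rep(n_class %/% config$n_users, config$n_users) +
      (seq_len(config$n_users) <= n_class %% config$n_users)
    for (iu in seq_len(config$n_users)) {
      if (per_user[iu] == 0) next
      tilt <- user_tilt(iu)
      Q <- rotation_matrix(tilt$u, tilt$theta)
      for (r in seq_len(per_user[iu])) {
        # motif draw keyed by (activity, replicate): shared across users
        motif <- with_seed(derive_seed(config$seed, "motif", ia, r), {
          len <- sample(config$segment_length_range[1]:config$segment_length_range[2], 1)
          list(len = len,
               ph = stats::runif(6, 0, 2 * pi),
               amp_jit = stats::rnorm(1, 1, 0.1),
               freq_jit = stats::rnorm(1, 1, 0.05))
        })
        t <- (0:(motif$len - 1)) / config$fs
        f <- mp$freq * motif$freq_jit
        xyz <- vapply(1:3, function(j) {
          motif$amp_jit * (mp$amp1[j] * sin(2 * pi * f * t + motif$ph[j]) +
                           mp$amp2[j] * sin(2 * pi * 2 * f * t + motif$ph[j + 3]))
        }, numeric(motif$len))
        xyz[, 3] <- xyz[, 3] + 1  # gravity-like offset before tilt
        xyz <- xyz %*% Q
        if (config$noise_sd > 0) {
          xyz <- xyz + with_seed(derive_seed(config$seed, "noise", ia, iu, r),
                                 matrix(stats::rnorm(length(xyz), 0, config$noise_sd),
                                        nrow = motif$len))
        }
        if (config$missing_rate > 0) {
          mask <- with_seed(derive_seed(config$seed, "missing", ia, iu, r),
                            matrix(stats::runif(length(xyz)) < config$missing_rate,
                                   nrow = motif$len))
          xyz[mask] <- NA_real_
        }
        k <- k + 1L
        segs[[k]] <- segment(xyz, fs = config$fs,
                             activity_id = sprintf("A%d", ia),
                             user_id = sprintf("U%d", iu),
                             uid = sprintf("syn-a%d-u%d-r%03d", ia, iu, r))
      }
    }
  }
  segment_set(segs)
}

#' Blank acceleration cells at random
#'
#' Each `ax`/`ay`/`az` cell is independently set to `NA` with probability
#' `rate`; used to exercise the imputation path.
#'
#' @param samples Raw-sample data frame.
#' @param rate Blanking probability in `[0, 1)`.
#' @param seed Integer seed or `NULL`.
#' @return The data frame with blanked cells.
#' @export
inject_missing <- function(samples, rate, seed = NULL) {
  check(rate >= 0 && rate < 1, "inject_missing: rate must be in [0, 1)")
  if (rate == 0) return(samples)
  n <- nrow(samples)
  mask <- with_seed(seed, matrix(stats::runif(3 * n) < rate, nrow = n))
  for (j in 1:3) {
    a <- c("ax", "ay", "az")[j]
    samples[[a]][mask[, j]] <- NA_real_
  }
  samples
}

#' Write a segment set as challenge-style sensor + label CSVs
#'
#' Dialect `ds1` writes `{segment_id, elapsed_time, ax, ay, az}` plus a
#' one-row-per-segment label file; dialect `ds2` writes
#' `{timestamp, ax, ay, az}` (segments laid out on disjoint time blocks) plus
#' interval labels. The files are readable by [read_sensor_csv()] /
#' [read_label_csv()] / [merge_labels()] and reproduce labels and values.
#'
#' @param set A `har_segmentset`.
#' @param dialect `"ds1"` or `"ds2"`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector with the `sensor` and `labels` paths.
#' @export
emit_challenge_csv <- function(set, dialect = c("ds1", "ds2"), out_dir) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sensor_path <- file.path(out_dir, sprintf("%s_sensor.csv", dialect))
  label_path <- file.path(out_dir, sprintf("%s_labels.csv", dialect))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  sensor_rows <- list(); label_rows <- list()
  for (i in seq_along(set$segments)) {
    s <- set$segments[[i]]
    n <- nrow(s$xyz)
    if (dialect == "ds1") {
      sensor_rows[[i]] <- data.frame(segment_id = i, elapsed_time = (0:(n - 1)) / s$fs,
                                     ax = s$xyz[, 1], ay = s$xyz[, 2], az = s$xyz[, 3])
      label_rows[[i]] <- data.frame(user_id = s$user_id, segment_id = i,
                                    activity_id = s$activity_id)
    } else {
      t0 <- (i - 1) * 1e4
      ts <- t0 + (0:(n - 1)) / s$fs
      sensor_rows[[i]] <- data.frame(timestamp = ts,
                                     ax = s$xyz[, 1], ay = s$xyz[, 2], az = s$xyz[, 3])
      label_rows[[i]] <- data.frame(user_id = s$user_id, activity_id = s$activity_id,
                                    start_time = ts[1], finish_time = ts[n])
    }
  }
  sensor <- do.call(rbind, sensor_rows)
  labels <- do.call(rbind, label_rows)
  if (is.null(sensor)) {
    sensor <- if (dialect == "ds1") {
      data.frame(segment_id = integer(), elapsed_time = numeric(),
                 ax = numeric(), ay = numeric(), az = numeric())
    } else {
      data.frame(timestamp = numeric(), ax = numeric(), ay = numeric(), az = numeric())
    }
    labels <- if (dialect == "ds1") {
      data.frame(user_id = character(), segment_id = integer(), activity_id = character())
    } else {
      data.frame(user_id = character(), activity_id = character(),
                 start_time = numeric(), finish_time = numeric())
    }
  } else {
    for (a in intersect(c("elapsed_time", "timestamp", "ax", "ay", "az",
                          "start_time", "finish_time"), names(sensor))) {
      sensor[[a]] <- fmt(sensor[[a]])
    }
    for (a in intersect(c("start_time", "finish_time"), names(labels))) {
      labels[[a]] <- fmt(labels[[a]])
    }
  }
  utils::write.csv(sensor, sensor_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(labels, label_path, row.names = FALSE, quote = FALSE)
  c(sensor = sensor_path, labels = label_path)
}
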