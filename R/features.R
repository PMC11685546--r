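#' Per-sample acceleration magnitude
#'
#' The L2 norm `sqrt(ax^2 + ay^2 + az^2)` of each sample; an
#' orientation-independent representation of the signal (rotating the sensor
#' leaves it unchanged).
#'
#' @param seg A [segment()] or an n x 3 numeric matrix.
#' @return Numeric series of length n.
#' @export
compute_magnitude <- function(seg) {
  xyz <- if (inherits(seg, "har_segment")) seg$xyz else as.matrix(seg)
  sqrt(rowSums(xyz^2))
}

#' Per-sample orientation angles
#'
#' For each axis `a`, `theta_a = arctan(a / sqrt(b^2 + c^2))` where `b`, `c`
#' are the other two axes. The all-zero sample maps to 0 by convention; a zero
#' denominator with a non-zero numerator yields the arctan limit `+/- pi/2`.
#'
#' @param seg A [segment()] or an n x 3 numeric matrix.
#' @return An n x 3 matrix with columns `angle_x`, `angle_y`, `angle_z`,
#'   values in `[-pi/2, pi/2]`.
#' @export
compute_angles <- function(seg) {
  xyz <- if (inherits(seg, "har_segment")) seg$xyz else as.matrix(seg)
  one_axis <- function(num, oth1, oth2) {
    den <- sqrt(oth1^2 + oth2^2)
    out <- atan(num / den)
    zero_den <- den == 0
    out[zero_den] <- sign(num[zero_den]) * pi / 2  # sign(0) = 0 handles (0,0,0)
    out
  }
  cbind(angle_x = one_axis(xyz[, 1], xyz[, 2], xyz[, 3]),
        angle_y = one_axis(xyz[, 2], xyz[, 1], xyz[, 3]),
        angle_z = one_axis(xyz[, 3], xyz[, 1], xyz[, 2]))
}

#' Cumulative trapezoidal integration
#'
#' First-order integration turns acceleration into velocity; applying the same
#' operator twice (`order = 2`) yields displacement. The integral starts at 0
#' and the output has the same length as the input.
#'
#' @param x Numeric series.
#' @param dt Sample spacing in seconds (`1 / fs`).
#' @param order 1 (single integral) or 2 (double integral).
#' @return Integrated series.
#' @export
#' @examples
#' integrate_series(rep(1, 5), dt = 1)        # 0 1 2 3 4
integrate_series <- function(x, dt, order = 1) {
  check(dt > 0, "integrate_series: dt must be > 0")
  check(order %in% c(1, 2), "integrate_series: order must be 1 or 2")
  cumtrapz <- function(v) {
    n <- length(v)
    if (n < 2) return(rep(0, n))
    c(0, cumsum((v[-1] + v[-n]) / 2)) * dt
  }
  y <- cumtrapz(x)
  if (order == 2) y <- cumtrapz(y)
  y
}

#' The 13-column intermediate feature set (IFS) of a segment
#'
#' Columns, in canonical order: the three (filtered) acceleration axes,
#' the magnitude, per-axis displacement (double integral), per-axis velocity
#' (single integral), and per-axis orientation angle.
#'
#' @param seg A filtered [segment()] (see [filter_segment()]).
#' @return An n x 13 numeric matrix with canonical column names.
#' @export
compute_ifs <- function(seg) {
  xyz <- seg$xyz
  dt <- 1 / seg$fs
  vel <- apply(xyz, 2, integrate_series, dt = dt, order = 1)
  disp <- apply(xyz, 2, integrate_series, dt = dt, order = 2)
  out <- cbind(xyz,
               magnitude = compute_magnitude(xyz),
               disp, vel, compute_angles(xyz))
  colnames(out) <- ifs_columns()
  out
}

#' @rdname compute_ifs
#' @export
ifs_columns <- function() {
  c("ax", "ay", "az", "magnitude",
    "disp_x", "disp_y", "disp_z",
    "vel_x", "vel_y", "vel_z",
    "angle_x", "angle_y", "angle_z")
}

# strict interior relative extrema of a series; plateaus contribute their
# first index only. Returns indices and type (+1 max / -1 min), alternating.
find_extrema <- function(x) {
  d <- diff(x)
  keep <- which(d != 0)
  if (length(keep) < 2) return(list(idx = integer(0), type = integer(0)))
  s <- sign(d[keep])
  flips <- which(s[-1] != s[-length(s)])
  idx <- keep[flips] + 1L
  type <- ifelse(s[flips] > 0, 1L, -1L)  # rising then falling = maximum
  list(idx = idx, type = as.integer(type))
}

#' MSUM: mean gap between extrema and their second-successive opposites
#'
#' Locates all strict interior relative maxima and minima. Each relative
#' maximum is connected to its second-successive relative minimum and each
#' relative minimum to its second-successive relative maximum; the absolute
#' value differences of all such lines are summed and divided by the number of
#' lines. Extrema lacking a second successor are skipped; a series with no
#' complete line returns 0. Because only value differences enter, MSUM is
#' invariant to constant shifts. The statistic summarises short- and
#' long-range alternation structure of composite movements.
#'
#' @param x Numeric series.
#' @return A single non-negative number.
#' @export
#' @examples
#' msum(sin(seq(0, 8 * pi, length.out = 200)))
#' msum(1:10)  # monotone: no interior extrema, 0
msum <- function(x) {
  ex <- find_extrema(x)
  t_ <- length(ex$idx)
  if (t_ < 4) return(0)
  # extrema alternate strictly, so the second successive opposite-type
  # extremum of e[j] is e[j + 3]
  v <- x[ex$idx]
  gaps <- abs(v[seq_len(t_ - 3)] - v[seq_len(t_ - 3) + 3])
  sum(gaps) / length(gaps)
}

#' The 117-value final feature set (FFS) of a segment
#'
#' For each of the 13 intermediate columns, nine statistics are computed:
#' standard deviation, average, max, min, variance, median absolute deviation
#' (`median(|x - median(x)|)`, unscaled), [msum()], energy (mean of squared
#' values, length-invariant) and interquartile range (linear-interpolation
#' quantiles). Names are `"<column>_<stat>"` in a fixed order.
#'
#' @param ifs An IFS matrix from [compute_ifs()].
#' @return Named numeric vector of length 117.
#' @export
compute_ffs <- function(ifs) {
  check(ncol(ifs) == 13, "compute_ffs: expected a 13-column IFS matrix")
  stats_one <- function(x) {
    s <- stats::sd(x)
    c(sd = s, avg = mean(x), max = max(x), min = min(x), var = s^2,
      mad = stats::median(abs(x - stats::median(x))), msum = msum(x),
      energy = mean(x^2),
      iqr = unname(stats::quantile(x, 0.75, type = 7) -
                   stats::quantile(x, 0.25, type = 7)))
  }
  vals <- lapply(seq_len(13), function(j) stats_one(ifs[, j]))
  out <- unlist(vals)
  names(out) <- as.vector(t(outer(colnames(ifs), ffs_stats(), paste, sep = "_")))
  out
}

#' @rdname compute_ffs
#' @export
ffs_stats <- function() {
  c("sd", "avg", "max", "min", "var", "mad", "msum", "energy", "iqr")
}

#' Build the per-segment feature table of a segment set
#'
#' Applies the full extraction chain per segment — median filter, zero-phase
#' Butterworth low-pass, 13-column intermediate features, 117 final features —
#' and stacks one labelled row per segment.
#'
#' @param set A `har_segmentset`.
#' @param filter Apply [filter_segment()] first (default `TRUE`).
#' @param median_window,cutoff,order Filter settings.
#' @return A data frame with 117 feature columns plus `activity_id`,
#'   `user_id`, `segment_uid`.
#' @export
build_feature_table <- function(set, filter = TRUE,
                                median_window = 5, cutoff = 20, order = 3) {
  check(length(set) > 0, "build_feature_table: empty segment set")
  rows <- lapply(set$segments, function(s) {
    tryCatch({
      if (filter) s <- filter_segment(s, median_window, cutoff, order)
      compute_ffs(compute_ifs(s))
    }, error = function(e) {
      stop(sprintf("feature extraction failed for segment %s: %s",
                   s$uid, conditionMessage(e)), call. = FALSE)
    })
  })
  feat <- as.data.frame(do.call(rbind, rows))
  feat$activity_id <- activities(set)
  feat$user_id <- users(set)
  feat$segment_uid <- segment_uids(set)
  rownames(feat) <- NULL
  feat
}

#' Names of the feature columns of a feature table
#' @param table A feature table from [build_feature_table()].
#' @return Character vector of feature column names (label columns excluded).
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("activity_id", "user_id", "segment_uid"))
}
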