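#' Construct a labelled acceleration segment
#'
#' A segment is the unit of classification: one contiguous window of tri-axial
#' acceleration carrying a single activity and user label.
#'
#' @param xyz Numeric matrix with `n >= 2` rows and columns `ax`, `ay`, `az`
#'   (acceleration in g or m/s^2; the package is unit-agnostic).
#' @param fs Sampling rate in Hz, `> 0`.
#' @param activity_id,user_id Labels (coerced to character).
#' @param source_id Provenance: `"original"` or the augmentation operator that
#'   produced the segment (e.g. `"tw"`, `"mw+tw"`).
#' @param uid Unique segment identifier string.
#' @param parent_uid For augmented segments, the uid of the source segment.
#' @return An object of class `har_segment`.
#' @export
#' @examples
#' s <- segment(cbind(ax = sin(1:50), ay = cos(1:50), az = rep(1, 50)),
#'              fs = 60, activity_id = "A1", user_id = "U1")
#' nrow(s$xyz)
segment <- function(xyz, fs, activity_id, user_id,
                    source_id = "original", uid = NULL, parent_uid = NA_character_) {
  xyz <- as.matrix(xyz)
  check(is.numeric(xyz) && ncol(xyz) == 3, "segment: xyz must be an n x 3 numeric matrix")
  check(nrow(xyz) >= 2, "segment: need at least 2 samples, got %d", nrow(xyz))
  check(is.numeric(fs) && length(fs) == 1 && fs > 0, "segment: sampling rate must be > 0")
  dimnames(xyz) <- list(NULL, c("ax", "ay", "az"))
  if (is.null(uid)) uid <- sprintf("seg-%s", paste(sample.int(36, 8) - 1, collapse = ""))
  structure(
    list(xyz = xyz, fs = as.numeric(fs),
         activity_id = as.character(activity_id), user_id = as.character(user_id),
         source_id = as.character(source_id), uid = as.character(uid),
         parent_uid = as.character(parent_uid)),
    class = "har_segment"
  )
}

#' @export
print.har_segment <- function(x, ...) {
  cat(sprintf("<har_segment %s> %d samples @ %g Hz | activity=%s user=%s source=%s\n",
              x$uid, nrow(x$xyz), x$fs, x$activity_id, x$user_id, x$source_id))
  invisible(x)
}

#' Bundle segments into a segment set
#'
#' @param segments List of [segment()] objects.
#' @param log Optional named list of bookkeeping counts (e.g. dropped samples).
#' @return An object of class `har_segmentset`.
#' @export
segment_set <- function(segments, log = list()) {
  check(is.list(segments), "segment_set: segments must be a list")
  ok <- vapply(segments, inherits, logical(1), what = "har_segment")
  check(all(ok), "segment_set: all elements must be har_segment objects")
  structure(list(segments = segments, log = log), class = "har_segmentset")
}

#' @export
length.har_segmentset <- function(x) length(x$segments)

#' @export
`[.har_segmentset` <- function(x, i) segment_set(x$segments[i], log = x$log)

#' @export
print.har_segmentset <- function(x, ...) {
  cat(sprintf("<har_segmentset> %d segments\n", length(x)))
  if (length(x) > 0) {
    tab <- table(activity = activities(x))
    cat("  per-activity counts:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
    cat(sprintf("  users: %s\n", paste(sort(unique(users(x))), collapse = ", ")))
  }
  if (length(x$log)) {
    cat("  log:", paste(sprintf("%s=%s", names(x$log), unlist(x$log)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname segment_set
#' @param x A `har_segmentset`.
#' @export
activities <- function(x) vapply(x$segments, `[[`, character(1), "activity_id")

#' @rdname segment_set
#' @export
users <- function(x) vapply(x$segments, `[[`, character(1), "user_id")

#' @rdname segment_set
#' @export
segment_uids <- function(x) vapply(x$segments, `[[`, character(1), "uid")

#' Per-class segment counts
#'
#' @param x A `har_segmentset`.
#' @param by `"activity"` or `"user"`.
#' @return Named integer vector of counts.
#' @export
class_counts <- function(x, by = c("activity", "user")) {
  by <- match.arg(by)
  lab <- if (by == "activity") activities(x) else users(x)
  tab <- table(lab)
  stats::setNames(as.integer(tab), names(tab))
}

# ---- raw sample ingestion ---------------------------------------------------

parse_timestamps <- function(ts_raw) {
  num <- suppressWarnings(as.numeric(ts_raw))
  if (!anyNA(num[!is.na(ts_raw)])) return(num)
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y/%m/%d %H:%M:%OS")
  parse1 <- function(s) {
    tryCatch(as.numeric(as.POSIXct(s, tz = "UTC", tryFormats = fmts)),
             error = function(e) NA_real_)
  }
  parsed <- tryCatch(as.numeric(as.POSIXct(ts_raw, tz = "UTC", tryFormats = fmts)),
                     error = function(e) vapply(ts_raw, parse1, numeric(1),
                                                USE.NAMES = FALSE))
  bad <- which(!is.na(ts_raw) & is.na(parsed))
  if (length(bad) > 0) {
    stop(sprintf("unparseable timestamp at row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  parsed
}

#' Read a sensor CSV in one of the two supported dialects
#'
#' Dialect `ds1` carries `segment_id, elapsed_time, ax, ay, az`; dialect `ds2`
#' carries `timestamp, ax, ay, az` with ISO-8601 or numeric-second timestamps.
#' All timestamps are converted to numeric seconds.
#'
#' @param path CSV file path (comma separated, header row).
#' @param dialect `"ds1"` or `"ds2"`.
#' @return A data frame of raw samples with numeric acceleration columns.
#' @export
read_sensor_csv <- function(path, dialect = c("ds1", "ds2")) {
  dialect <- match.arg(dialect)
  check(file.exists(path), "read_sensor_csv: file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (dialect == "ds1") c("segment_id", "elapsed_time", "ax", "ay", "az")
          else c("timestamp", "ax", "ay", "az")
  miss <- setdiff(need, names(df))
  check(length(miss) == 0, "read_sensor_csv: missing required column(s): %s",
        paste(miss, collapse = ", "))
  df <- df[, need]
  if (dialect == "ds2") {
    df$timestamp <- parse_timestamps(df$timestamp)
    check(all(is.finite(df$timestamp)), "read_sensor_csv: non-finite timestamp present")
  } else {
    df$segment_id <- as.integer(df$segment_id)
    df$elapsed_time <- as.numeric(df$elapsed_time)
  }
  for (a in c("ax", "ay", "az")) df[[a]] <- as.numeric(df[[a]])
  df
}

#' Read a label CSV in one of the two supported dialects
#'
#' Dialect `ds1`: `user_id, segment_id, activity_id` (one row per segment).
#' Dialect `ds2`: `user_id, activity_id, start_time, finish_time` (one row per
#' labelled interval, closed on both ends).
#'
#' @inheritParams read_sensor_csv
#' @return A data frame of label records.
#' @export
read_label_csv <- function(path, dialect = c("ds1", "ds2")) {
  dialect <- match.arg(dialect)
  check(file.exists(path), "read_label_csv: file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (dialect == "ds1") c("user_id", "segment_id", "activity_id")
          else c("user_id", "activity_id", "start_time", "finish_time")
  miss <- setdiff(need, names(df))
  check(length(miss) == 0, "read_label_csv: missing required column(s): %s",
        paste(miss, collapse = ", "))
  df <- df[, need]
  if (dialect == "ds2") {
    df$start_time <- parse_timestamps(df$start_time)
    df$finish_time <- parse_timestamps(df$finish_time)
    check(all(df$start_time <= df$finish_time),
          "read_label_csv: start_time must be <= finish_time for every interval")
  }
  df
}

#' Sort raw samples into canonical order
#'
#' Stable sort by `timestamp` (ds2) or by `(segment_id, elapsed_time)` (ds1);
#' duplicate keys keep their original relative order.
#'
#' @param samples Raw-sample data frame from [read_sensor_csv()].
#' @param dialect `"ds1"` or `"ds2"`.
#' @return The sorted data frame.
#' @export
normalize_and_sort <- function(samples, dialect = c("ds1", "ds2")) {
  dialect <- match.arg(dialect)
  if (nrow(samples) == 0) return(samples)
  ord <- if (dialect == "ds1") {
    order(samples$segment_id, samples$elapsed_time)  # radix sort: stable
  } else {
    order(samples$timestamp)
  }
  out <- samples[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean-impute missing acceleration values
#'
#' Each missing `ax`/`ay`/`az` cell is replaced by the mean of the non-missing
#' values of its own column; non-missing values are untouched.
#'
#' @param samples Raw-sample data frame.
#' @return The imputed data frame.
#' @export
impute_missing <- function(samples) {
  for (a in c("ax", "ay", "az")) {
    x <- samples[[a]]
    if (anyNA(x)) {
      check(!all(is.na(x)), "impute_missing: column '%s' is entirely missing", a)
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      samples[[a]] <- x
    }
  }
  samples
}

#' Merge raw samples with label records into labelled segments
#'
#' Dialect `ds1` joins on segment id (one segment per labelled id); dialect
#' `ds2` assigns each sample to the label interval with
#' `start_time <= t <= finish_time` (closed interval). Samples matching no
#' label are dropped and counted in the set's log.
#'
#' @param samples Sorted raw-sample data frame ([normalize_and_sort()]).
#' @param labels Label data frame ([read_label_csv()]).
#' @param dialect `"ds1"` or `"ds2"`.
#' @param fs Sampling rate in Hz (defaults: 4 for ds1, 60 for ds2).
#' @param overlap Policy for ds2 intervals claiming the same sample:
#'   `"error"` (default) or `"first"` (first interval in label order wins).
#' @return A [segment_set()] with one segment per labelled unit.
#' @export
merge_labels <- function(samples, labels, dialect = c("ds1", "ds2"),
                         fs = NULL, overlap = c("error", "first")) {
  dialect <- match.arg(dialect)
  overlap <- match.arg(overlap)
  if (is.null(fs)) fs <- if (dialect == "ds1") 4 else 60
  segs <- list()
  k <- 0L
  used <- rep(FALSE, nrow(samples))
  if (dialect == "ds1") {
    for (i in seq_len(nrow(labels))) {
      sel <- which(samples$segment_id == labels$segment_id[i])
      if (length(sel) < 2) next
      used[sel] <- TRUE
      k <- k + 1L
      segs[[k]] <- segment(as.matrix(samples[sel, c("ax", "ay", "az")]),
                           fs = fs, activity_id = labels$activity_id[i],
                           user_id = labels$user_id[i],
                           uid = sprintf("ds1-s%d", labels$segment_id[i]))
    }
  } else {
    claimed_by <- rep(NA_integer_, nrow(samples))
    for (i in seq_len(nrow(labels))) {
      sel <- which(samples$timestamp >= labels$start_time[i] &
                   samples$timestamp <= labels$finish_time[i])
      clash <- sel[!is.na(claimed_by[sel])]
      if (length(clash) > 0) {
        if (overlap == "error") {
          other <- unique(claimed_by[clash])
          stop(sprintf(paste0("merge_labels: label intervals overlap; interval %d ",
                              "claims %d sample(s) already claimed by interval(s) %s"),
                       i, length(clash), paste(other, collapse = ", ")), call. = FALSE)
        }
        sel <- sel[is.na(claimed_by[sel])]
      }
      if (length(sel) < 2) next
      claimed_by[sel] <- i
      used[sel] <- TRUE
      k <- k + 1L
      segs[[k]] <- segment(as.matrix(samples[sel, c("ax", "ay", "az")]),
                           fs = fs, activity_id = labels$activity_id[i],
                           user_id = labels$user_id[i],
                           uid = sprintf("ds2-l%04d", i))
    }
  }
  segment_set(segs, log = list(dropped_samples = sum(!used),
                               matched_samples = sum(used)))
}

#' Impute missing acceleration values inside segments, per user
#'
#' Column means are computed within each user's own samples, so no value from
#' one subject ever enters another subject's imputation (important for
#' leave-one-subject-out evaluation).
#'
#' @param set A `har_segmentset` possibly containing `NA` acceleration cells.
#' @return The set with all `NA` cells mean-imputed.
#' @export
impute_segments <- function(set) {
  us <- users(set)
  for (u in unique(us)) {
    idx <- which(us == u)
    pool <- do.call(rbind, lapply(set$segments[idx], `[[`, "xyz"))
    mu <- colMeans(pool, na.rm = TRUE)
    check(all(is.finite(mu)),
          "impute_segments: a column of user '%s' is entirely missing", u)
    for (i in idx) {
      xyz <- set$segments[[i]]$xyz
      for (j in 1:3) {
        nas <- is.na(xyz[, j])
        if (any(nas)) xyz[nas, j] <- mu[j]
      }
      set$segments[[i]]$xyz <- xyz
    }
  }
  set
}

#' Slice segments into fixed-length sliding windows
#'
#' Segments longer than `window` are replaced by sliding windows of exactly
#' `window` samples (stride `stride`), inheriting labels and provenance.
#' Shorter segments are kept whole (`short = "keep"`) or dropped
#' (`short = "drop"`, counted in the log).
#'
#' @param set A `har_segmentset`.
#' @param window Window length in samples (`>= 2`).
#' @param stride Stride in samples (`>= 1`); defaults to `window`.
#' @param short Policy for segments shorter than `window`.
#' @return A windowed `har_segmentset`.
#' @export
window_segments <- function(set, window, stride = window,
                            short = c("keep", "drop")) {
  short <- match.arg(short)
  check(window >= 2, "window_segments: window must be >= 2")
  check(stride >= 1, "window_segments: stride must be >= 1")
  out <- list()
  k <- 0L
  dropped <- 0L
  for (s in set$segments) {
    n <- nrow(s$xyz)
    if (n < window) {
      if (short == "drop") { dropped <- dropped + 1L; next }
      k <- k + 1L
      out[[k]] <- s
      next
    }
    starts <- seq(1L, n - window + 1L, by = stride)
    for (w in seq_along(starts)) {
      k <- k + 1L
      out[[k]] <- segment(s$xyz[starts[w]:(starts[w] + window - 1L), , drop = FALSE],
                          fs = s$fs, activity_id = s$activity_id, user_id = s$user_id,
                          source_id = s$source_id,
                          uid = sprintf("%s.w%03d", s$uid, w),
                          parent_uid = s$uid)
    }
  }
  segment_set(out, log = c(set$log, list(short_dropped = dropped)))
}

# ---- segment store ----------------------------------------------------------

#' Write / read the flat segment store
#'
#' One CSV row per sample: `segment_uid, sample_idx, ax, ay, az, activity_id,
#' user_id, source_id`, plus a JSON manifest (`<path>.json`) recording the
#' sampling rate and log counts. Acceleration values round-trip bit-identically
#' (written with full precision).
#'
#' @param set A `har_segmentset`.
#' @param path Output CSV path.
#' @return `write_segments` returns `path` invisibly; `read_segments` returns
#'   the reconstructed `har_segmentset`.
#' @export
write_segments <- function(set, path) {
  rows <- lapply(set$segments, function(s) {
    data.frame(segment_uid = s$uid, sample_idx = seq_len(nrow(s$xyz)),
               ax = s$xyz[, 1], ay = s$xyz[, 2], az = s$xyz[, 3],
               activity_id = s$activity_id, user_id = s$user_id,
               source_id = s$source_id, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(segment_uid = character(), sample_idx = integer(),
                     ax = numeric(), ay = numeric(), az = numeric(),
                     activity_id = character(), user_id = character(),
                     source_id = character())
  }
  # format with full double precision so the round trip is exact
  for (a in c("ax", "ay", "az")) df[[a]] <- sprintf("%.17g", df[[a]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  fs <- if (length(set) > 0) set$segments[[1]]$fs else NA_real_
  jsonlite::write_json(list(sampling_rate = fs, n_segments = length(set), log = set$log),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  man_path <- paste0(path, ".json")
  fs <- if (file.exists(man_path)) {
    v <- jsonlite::read_json(man_path)$sampling_rate
    if (is.null(v)) 60 else as.numeric(v)
  } else 60
  segs <- lapply(split(df, factor(df$segment_uid, levels = unique(df$segment_uid))),
                 function(d) {
    d <- d[order(d$sample_idx), , drop = FALSE]
    segment(as.matrix(d[, c("ax", "ay", "az")]), fs = fs,
            activity_id = d$activity_id[1], user_id = d$user_id[1],
            source_id = d$source_id[1], uid = d$segment_uid[1])
  })
  names(segs) <- NULL
  segment_set(segs)
}
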