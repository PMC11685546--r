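#' Label-preserving augmentation operators for acceleration segments
#'
#' Five operators emulate real-world nuisance variation without altering the
#' activity/user label or the segment length: additive Gaussian noise
#' ([jitter()]), multiplicative Gaussian noise ([scaling()]), elementwise
#' multiplication by a smooth random curve around one ([magnitude_warp()]),
#' resampling along a randomly warped time base ([time_warp()]), and a random
#' 3-D rotation of the sensor frame ([rotation()]).
#'
#' Unstated Gaussian parameters default to values from the wearable
#' augmentation literature: jitter `N(0, 0.03 * sd(signal))`, scaling
#' `N(1, 0.1)`, warp-knot values `N(1, 0.2)` with curve complexity `phi = 4`.
#' All operators are pure functions of `(input, parameters, seed)`.
#'
#' @param seg A [segment()].
#' @param mu,sigma Gaussian mean and standard deviation (see defaults above).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return The augmented segment (same length and labels, updated
#'   `source_id`/`parent_uid`).
#' @name augment-ops
NULL

mark_augmented <- function(seg, op) {
  seg$parent_uid <- seg$uid
  seg$uid <- paste(seg$uid, op, sep = ".")
  seg$source_id <- op
  seg
}

#' @rdname augment-ops
#' @export
jitter <- function(seg, mu = 0, sigma = NULL, seed = NULL) {
  if (is.null(sigma)) sigma <- 0.03 * stats::sd(seg$xyz)
  check(sigma >= 0, "jitter: sigma must be >= 0")
  noise <- with_seed(seed, matrix(stats::rnorm(length(seg$xyz), mu, sigma),
                                  nrow = nrow(seg$xyz)))
  seg$xyz <- seg$xyz + noise
  mark_augmented(seg, "jitter")
}

#' @rdname augment-ops
#' @export
scaling <- function(seg, mu = 1, sigma = 0.1, seed = NULL) {
  check(sigma >= 0, "scaling: sigma must be >= 0")
  w <- with_seed(seed, matrix(stats::rnorm(length(seg$xyz), mu, sigma),
                              nrow = nrow(seg$xyz)))
  seg$xyz <- seg$xyz * w
  mark_augmented(seg, "scaling")
}

#' Smooth random curve by natural cubic spline through Gaussian knots
#'
#' Draws `phi + 2` knot values from `N(mu, sigma)` at equally spaced positions
#' spanning `[0, m - 1]` and returns the natural cubic spline through them,
#' evaluated at the integer positions `0 .. m - 1`. The curve passes through
#' the knots exactly.
#'
#' @param m Output length (`>= 2`).
#' @param phi Curve complexity; the knot count is `phi + 2`.
#' @param mu,sigma Knot-value Gaussian parameters.
#' @param seed Integer seed or `NULL`.
#' @return Numeric series of length `m`.
#' @export
random_curve <- function(m, phi = 4, mu = 1, sigma = 0.2, seed = NULL) {
  check(m >= 2, "random_curve: m must be >= 2")
  check(phi >= 1, "random_curve: phi must be >= 1")
  k <- phi + 2
  xk <- seq(0, m - 1, length.out = k)
  yk <- with_seed(seed, stats::rnorm(k, mu, sigma))
  stats::spline(xk, yk, xout = 0:(m - 1), method = "natural")$y
}

#' @rdname augment-ops
#' @param phi Curve complexity (knot count `phi + 2`) for the warp operators.
#' @export
magnitude_warp <- function(seg, phi = 4, mu = 1, sigma = 0.2, seed = NULL) {
  curve <- random_curve(nrow(seg$xyz), phi = phi, mu = mu, sigma = sigma, seed = seed)
  seg$xyz <- seg$xyz * curve  # one curve shared across axes
  mark_augmented(seg, "mw")
}

#' @rdname augment-ops
#' @param max_retries Redraw budget for non-monotone warp curves.
#' @export
time_warp <- function(seg, phi = 4, mu = 1, sigma = 0.2, seed = NULL,
                      max_retries = 10) {
  m <- nrow(seg$xyz)
  check(m >= 2, "time_warp: segment must have >= 2 samples")
  draw <- function(s) random_curve(m, phi = phi, mu = mu, sigma = sigma, seed = s)
  r <- draw(seed)
  tries <- 0
  while (any(r[-1] <= 0) && tries < max_retries) {
    tries <- tries + 1
    r <- draw(if (is.null(seed)) NULL else seed + 1000003L * tries)
  }
  check(all(r[-1] > 0),
        "time_warp: could not draw a monotone warp curve in %d retries", max_retries)
  v <- cumsum(r) / m                    # cumulative-average warp
  vs <- (v - v[1]) / (v[m] - v[1]) * (m - 1)  # rescaled to span the index range
  grid <- 0:(m - 1)
  for (j in 1:3) {
    seg$xyz[, j] <- stats::approx(vs, seg$xyz[, j], xout = grid)$y
  }
  mark_augmented(seg, "tw")
}

#' Rotation matrix from an axis-angle draw
#'
#' Axis-angle rotation matrix `Q` for unit axis `u = (x, y, z)` and angle
#' `theta`; samples are rotated as row vectors, `sample %*% Q`.
#'
#' @param u Unit 3-vector (axis).
#' @param theta Rotation angle in radians.
#' @return A 3 x 3 orthogonal matrix.
#' @export
rotation_matrix <- function(u, theta) {
  check(abs(sqrt(sum(u^2)) - 1) < 1e-9, "rotation_matrix: u must be a unit vector")
  x <- u[1]; y <- u[2]; z <- u[3]
  cc <- 1 - cos(theta); s <- sin(theta); co <- cos(theta)
  matrix(c(x * x * cc + co,     x * y * cc - z * s,  x * z * cc + y * s,
           y * x * cc + z * s,  y * y * cc + co,     y * z * cc - x * s,
           z * x * cc - y * s,  z * y * cc + x * s,  z * z * cc + co),
         nrow = 3, byrow = TRUE)
}

#' @rdname augment-ops
#' @export
rotation <- function(seg, seed = NULL) {
  draw <- with_seed(seed, {
    repeat {
      u <- stats::runif(3, -1, 1)
      nu <- sqrt(sum(u^2))
      if (nu > 1e-8) break
    }
    list(u = u / nu, theta = stats::runif(1, -pi, pi))
  })
  Q <- rotation_matrix(draw$u, draw$theta)
  seg$xyz <- seg$xyz %*% Q
  colnames(seg$xyz) <- c("ax", "ay", "az")
  mark_augmented(seg, "rot")
}

#' Augmentation plan for class balancing
#'
#' @param A Target number of segments per class; must be at least the current
#'   maximum class count. The headline experiments enlarge the data set to 3x
#'   the original majority count.
#' @param types Character vector of operator names among `"jitter"`,
#'   `"scaling"`, `"mw"`, `"tw"`, `"rot"`; a pair such as `"mw+tw"` means
#'   composition, applied left to right.
#' @param params Named list of per-operator parameter lists (e.g.
#'   `list(tw = list(sigma = 0.2))`).
#' @param seed Integer root seed for all augmentation draws.
#' @return An object of class `har_plan`.
#' @export
augmentation_plan <- function(A, types = "tw", params = list(), seed = 1) {
  check(length(types) >= 1, "augmentation_plan: types must be non-empty")
  atoms <- unique(unlist(strsplit(types, "+", fixed = TRUE)))
  bad <- setdiff(atoms, c("jitter", "scaling", "mw", "tw", "rot"))
  check(length(bad) == 0, "augmentation_plan: unknown augmentation type(s): %s",
        paste(bad, collapse = ", "))
  structure(list(A = as.integer(A), types = types, params = params,
                 seed = as.integer(seed)), class = "har_plan")
}

apply_augmentation <- function(seg, type, params, seed) {
  atoms <- strsplit(type, "+", fixed = TRUE)[[1]]
  for (i in seq_along(atoms)) {
    op <- atoms[i]
    p <- params[[op]] %||% list()
    s <- derive_seed(seed, op, i)
    seg <- switch(op,
      jitter  = do.call(jitter,  c(list(seg = seg, seed = s), p)),
      scaling = do.call(scaling, c(list(seg = seg, seed = s), p)),
      mw      = do.call(magnitude_warp, c(list(seg = seg, seed = s), p)),
      tw      = do.call(time_warp,      c(list(seg = seg, seed = s), p)),
      rot     = do.call(rotation, c(list(seg = seg, seed = s), p)))
  }
  if (length(atoms) > 1) seg$source_id <- type
  seg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Balance class sizes by cycled augmentation
#'
#' Groups segments by class label, then cycles over each group's original
#' segments applying the planned augmentation(s) until every class holds
#' exactly `plan$A` segments. Originals are retained unmodified; augmented
#' segments carry the operator name as `source_id` and their source segment as
#' `parent_uid`.
#'
#' @param set A `har_segmentset` with every class non-empty.
#' @param plan An [augmentation_plan()].
#' @param by Grouping label: `"activity"` (default) or `"user"`.
#' @return The balanced `har_segmentset` (originals first, augmented appended).
#' @export
balance_augment <- function(set, plan, by = c("activity", "user")) {
  by <- match.arg(by)
  check(inherits(plan, "har_plan"), "balance_augment: plan must be an augmentation_plan()")
  labs <- if (by == "activity") activities(set) else users(set)
  counts <- table(labs)
  check(all(counts > 0), "balance_augment: empty class present")
  check(plan$A >= max(counts),
        "balance_augment: A = %d is below the current maximum class count %d",
        plan$A, max(counts))
  aug <- list()
  k <- 0L
  for (cl in names(counts)) {
    members <- which(labs == cl)
    need <- plan$A - length(members)
    i <- 0L
    while (need > 0L) {
      src <- set$segments[[members[(i %% length(members)) + 1L]]]
      type <- plan$types[(i %% length(plan$types)) + 1L]
      s <- apply_augmentation(src, type, plan$params,
                              seed = derive_seed(plan$seed, cl, i))
      s$uid <- sprintf("%s.aug%04d", src$uid, i)
      k <- k + 1L
      aug[[k]] <- s
      i <- i + 1L
      need <- need - 1L
    }
  }
  segment_set(c(set$segments, aug), log = set$log)
}
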