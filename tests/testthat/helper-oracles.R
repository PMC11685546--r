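# Independent oracles and fixture builders shared across the test files.
# Both oracles are written directly from first principles and deliberately
# share no code with the implementations they check.

with_seed <- carehar:::with_seed

# natural cubic spline through (xk, yk), evaluated at xout, via the classical
# tridiagonal second-derivative system (M_0 = M_{k-1} = 0)
natural_spline_oracle <- function(xk, yk, xout) {
  k <- length(xk)
  h <- diff(xk)
  M <- numeric(k)
  if (k > 2) {
    A <- matrix(0, k - 2, k - 2)
    rhs <- numeric(k - 2)
    for (i in 1:(k - 2)) {
      if (i > 1) A[i, i - 1] <- h[i]
      A[i, i] <- 2 * (h[i] + h[i + 1])
      if (i < k - 2) A[i, i + 1] <- h[i + 1]
      rhs[i] <- 6 * ((yk[i + 2] - yk[i + 1]) / h[i + 1] - (yk[i + 1] - yk[i]) / h[i])
    }
    M[2:(k - 1)] <- solve(A, rhs)
  }
  vapply(xout, function(t) {
    i <- max(1, min(k - 1, findInterval(t, xk)))
    hh <- h[i]
    a <- (xk[i + 1] - t) / hh
    b <- (t - xk[i]) / hh
    a * yk[i] + b * yk[i + 1] +
      ((a^3 - a) * M[i] + (b^3 - b) * M[i + 1]) * hh^2 / 6
  }, numeric(1))
}

# literal extremum-pairing reading of the MSUM definition: locate strict
# relative maxima/minima, then for every maximum walk forward to its *second*
# following minimum (and vice versa), summing absolute value gaps
msum_oracle <- function(x) {
  n <- length(x)
  idx <- integer(0); type <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) { idx <- c(idx, i); type <- c(type, 1L) }
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) { idx <- c(idx, i); type <- c(type, -1L) }
  }
  gaps <- numeric(0)
  for (e in seq_along(idx)) {
    seen <- 0L
    for (f in seq_along(idx)) {
      if (f > e && type[f] == -type[e]) {
        seen <- seen + 1L
        if (seen == 2L) {
          gaps <- c(gaps, abs(x[idx[e]] - x[idx[f]]))
          break
        }
      }
    }
  }
  if (length(gaps) == 0) 0 else sum(gaps) / length(gaps)
}

# small random segment
make_seg <- function(n = 80, fs = 60, seed = 1, activity = "A1", user = "U1") {
  set.seed(seed)
  segment(cbind(ax = stats::rnorm(n), ay = stats::rnorm(n), az = stats::rnorm(n)),
          fs = fs, activity_id = activity, user_id = user,
          uid = sprintf("fix-%d", seed))
}

# write a small ds2 sensor CSV and return its path
write_ds2_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  p
}
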