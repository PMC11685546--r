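#' Centered running-median filter
#'
#' Window size 5 by default; edges are handled by shrinking the window
#' symmetrically, so output length equals input length.
#'
#' @param x Numeric series.
#' @param window Odd window size (`1` = identity).
#' @return Filtered series.
#' @export
#' @examples
#' median_filter(c(0, 0, 9, 0, 0))  # lone spike removed
median_filter <- function(x, window = 5) {
  check(window >= 1 && window %% 2 == 1, "median_filter: window must be odd and >= 1")
  if (window == 1 || length(x) < 3) return(x)
  window <- min(window, if (length(x) %% 2 == 1) length(x) else length(x) - 1)
  as.numeric(stats::runmed(x, k = window, endrule = "median"))
}

# polynomial coefficients (highest order first) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0) - ri * c(0, p)
  p
}

# digital order-n Butterworth low-pass via bilinear transform with prewarping;
# returns list(b, a), a[1] = 1, exact unit DC gain
butter_design <- function(order, cutoff, fs) {
  wa <- 2 * fs * tan(pi * cutoff / fs)
  k <- seq_len(order)
  p_analog <- wa * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  zp <- (2 * fs + p_analog) / (2 * fs - p_analog)
  a <- Re(poly_from_roots(zp))
  b0 <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b0 * sum(a) / sum(b0)
  list(b = b / a[1], a = a / a[1])
}

# direct-form II transposed IIR filter with optional initial state
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) {
      for (j in 1:(n - 2)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    }
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# steady-state initial filter state for a unit step input
iir_filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  comp <- matrix(0, n - 1, n - 1)  # companion matrix of a
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(comp), B)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Order-3 Butterworth applied forward and backward (zero phase, squared
#' magnitude response), with odd-extension padding and steady-state initial
#' conditions to suppress edge transients. DC gain is exactly 1. When the
#' cutoff is at or above the Nyquist frequency the filter is mathematically
#' void and the input is returned unchanged with a warning (this is the case
#' for 4 Hz data with the default 20 Hz cutoff).
#'
#' @param x Numeric series (finite).
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (default 20, the upper edge of the
#'   human-motion band).
#' @param order Filter order (default 3).
#' @return Filtered series of the same length.
#' @export
butterworth_lowpass <- function(x, fs, cutoff = 20, order = 3) {
  check(all(is.finite(x)), "butterworth_lowpass: input contains non-finite values")
  check(fs > 0, "butterworth_lowpass: fs must be > 0")
  if (cutoff >= fs / 2) {
    warning(sprintf("cutoff %g Hz >= Nyquist %g Hz; filter skipped", cutoff, fs / 2))
    return(x)
  }
  co <- butter_design(order, cutoff, fs)
  n <- length(x)
  padlen <- min(n - 1, 3 * (length(co$a)))
  if (padlen < 1) return(x)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- iir_filter_zi(co$b, co$a)
  y <- iir_filter(co$b, co$a, ext, zi = zi * ext[1])
  y <- rev(y)
  y <- iir_filter(co$b, co$a, y, zi = zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Analytic squared magnitude response of the zero-phase Butterworth
#'
#' For an order-`n` analog Butterworth low-pass,
#' `|H(f)|^2 = 1 / (1 + (f/fc)^(2n))`; the forward-backward application
#' squares the single-pass magnitude, and this function returns that two-pass
#' gain. When `fs` is supplied, the exact response of the *digital* filter
#' obtained by the bilinear transform with prewarping is returned instead:
#' the frequency axis is warped as `tan(pi f / fs) / tan(pi fc / fs)`, which
#' matters close to Nyquist (at 25 Hz with `fs = 60` the digital filter
#' attenuates far more than the analog formula suggests). Useful as an
#' independent closed-form check of [butterworth_lowpass()] attenuation.
#'
#' @param f Frequency in Hz.
#' @param cutoff Cutoff frequency in Hz.
#' @param order Filter order.
#' @param fs Sampling rate in Hz for the digital (prewarped) response;
#'   `NULL` gives the analog prototype response.
#' @return The two-pass amplitude gain `|H|^2` at `f`.
#' @export
butterworth_gain_twopass <- function(f, cutoff = 20, order = 3, fs = NULL) {
  ratio <- if (is.null(fs)) f / cutoff else tan(pi * f / fs) / tan(pi * cutoff / fs)
  1 / (1 + ratio^(2 * order))
}

#' Apply median + Butterworth filtering to every axis of a segment
#'
#' @param seg A [segment()].
#' @param median_window Median filter window (odd; default 5).
#' @param cutoff,order Butterworth settings (defaults 20 Hz, order 3).
#' @return The filtered segment.
#' @export
filter_segment <- function(seg, median_window = 5, cutoff = 20, order = 3) {
  for (j in 1:3) {
    v <- median_filter(seg$xyz[, j], window = median_window)
    if (cutoff < seg$fs / 2) v <- butterworth_lowpass(v, fs = seg$fs, cutoff = cutoff,
                                                      order = order)
    seg$xyz[, j] <- v
  }
  seg
}
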