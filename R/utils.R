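#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the previous
#' RNG state, so library functions stay pure in the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream as-is.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a child seed from a root seed and a named substream
#'
#' All randomness in the package flows from one root seed through named
#' substreams (simulate / augment / model-init / splits / ...). The derivation
#' is a small deterministic integer hash kept strictly below 2^31.
#'
#' @param seed Integer root seed.
#' @param ... Character or integer substream labels.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "simulate")
#' derive_seed(1, "augment", 7)
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (v in utf8ToInt(labels)) {
    h <- (h * 33 + v) %% 2147483647
  }
  as.integer(h)
}

# stopifnot-style check with a formatted message
check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}
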