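#' @importFrom stats cor rnorm runif sd setNames quantile
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Derive a reproducible sub-seed from a root seed and a stream name.
# Keeps every stage (cohort, splits, init, dropout, ...) on its own stream
# so changing one stage never perturbs another. Result is a valid 32-bit
# integer seed.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 7919)
  as.integer((abs(seed) * 48271 + h) %% 2147483629L + 1L)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is_square(m)) abort(sprintf("%s must be square", what))
  if (max(abs(m - t(m))) > tol) abort(sprintf("%s must be symmetric", what))
  invisible(TRUE)
}

check_nonnegative <- function(m, what = "matrix") {
  if (any(m < 0)) abort(sprintf("%s must have non-negative entries", what))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
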