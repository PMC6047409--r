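# internal helpers shared across modules

geometric_mean <- function(x) exp(mean(log(x)))

#' Derive a child RNG seed from a parent seed and stream indices
#'
#' Deterministic mixing of a base seed with up to two stream indices, used
#' to give every simulation cell, iteration and bootstrap window its own
#' reproducible substream. The result is always a valid 32-bit integer
#' seed.
#'
#' @param seed Integer base seed.
#' @param i,j Non-negative integer stream indices.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 1, 3)
derive_seed <- function(seed, i = 0L, j = 0L) {
  # 64-bit-safe affine hash folded into the 32-bit signed range
  m <- 2147483629
  s <- (as.numeric(seed) %% m)
  s <- (s * 69069 + as.numeric(i) * 7919 + 1) %% m
  s <- (s * 69069 + as.numeric(j) * 104729 + 1) %% m
  as.integer(s)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# column-wise variance of a matrix without extra dependencies
col_vars <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(NA_real_, ncol(m)))
  mu <- colMeans(m)
  colSums((m - rep(mu, each = n))^2) / (n - 1)
}

row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}
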