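# Welch t with an explicit zero-variance convention: a draw where both
# groups are constant is degenerate and carries no studentized evidence,
# so it maps to 0 rather than +-Inf (observed degenerate data are handled
# separately before resampling).
welch_t <- function(ma, mb, va, vb, na, nb) {
  num <- mb - ma
  den <- sqrt(va / na + vb / nb)
  out <- num / den
  out[den == 0] <- 0
  out
}

# all within-group resample index combinations, n^n rows of n columns
enumerate_indices <- function(n) {
  as.matrix(expand.grid(rep(list(seq_len(n)), n)))
}

# bootstrap p for one window; a, b already transformed.
# Null is enforced by centering each group at its own mean before
# resampling; p uses the (1 + k) / (B + 1) estimator.
bootstrap_p_one <- function(a, b, B, seed, enumerate = FALSE) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  t_obs <- welch_t(mean(a), mean(b), va, vb, na, nb)
  if (va == 0 && vb == 0) {
    # degenerate data: no resampling can inform the null
    n_eff <- if (enumerate) na^na * nb^nb else B
    return(list(t = t_obs, p = if (mean(a) == mean(b)) 1 else 1 / (n_eff + 1)))
  }
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  if (enumerate) {
    ia <- enumerate_indices(na)
    ib <- enumerate_indices(nb)
    grid <- expand.grid(ra = seq_len(nrow(ia)), rb = seq_len(nrow(ib)))
    am <- matrix(a0[t(ia[grid$ra, , drop = FALSE])], nrow = na)
    bm <- matrix(b0[t(ib[grid$rb, , drop = FALSE])], nrow = nb)
    Bn <- ncol(am)
  } else {
    set.seed(seed)
    am <- matrix(a0[sample.int(na, na * B, replace = TRUE)], nrow = na)
    bm <- matrix(b0[sample.int(nb, nb * B, replace = TRUE)], nrow = nb)
    Bn <- B
  }
  mas <- colMeans(am); mbs <- colMeans(bm)
  vas <- colSums((am - rep(mas, each = na))^2) / (na - 1)
  vbs <- colSums((bm - rep(mbs, each = nb))^2) / (nb - 1)
  tstar <- welch_t(mas, mbs, vas, vbs, na, nb)
  k <- sum(abs(tstar) >= abs(t_obs))
  list(t = t_obs, p = (1 + k) / (Bn + 1))
}

#' Bootstrap t test across windows
#'
#' Two-sample Welch t test whose null distribution is built by
#' resampling: each group is centred at its own mean (enforcing the
#' null), replicates are resampled with replacement within groups B
#' times, and the p-value is `(1 + #{|t*| >= |t_obs|}) / (B + 1)`. The
#' test operates on `log2(x + 0.5)` of the normalized counts by default.
#' Per-window RNG substreams are derived from `cfg$rng_seed` and the
#' window index, so results do not depend on evaluation order. With
#' `cfg$enumerate = TRUE` all `n_a^n_a * n_b^n_b` resample combinations
#' are evaluated exactly instead (tiny groups only).
#'
#' @inheritParams nb_exact_test
#' @param cfg A [test_config()]; `alpha`, `bootstrap_iterations`,
#'   `rng_seed`, `transform` and `enumerate` are used.
#' @return A `capwin_detection` tibble with `statistic` (observed Welch
#'   t), `p_value` and `is_significant` (`p < alpha`).
#' @export
bootstrap_t_test <- function(exp, group_a, group_b, cfg = test_config()) {
  validate_experiment(exp)
  ia <- group_columns(exp, group_a)
  ib <- group_columns(exp, group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    abort("bootstrap t test needs >= 2 replicates per group")
  }
  x <- transform_matrix(working_matrix(exp), cfg$transform)
  res <- purrr::map(seq_len(nrow(x)), function(w) {
    bootstrap_p_one(
      x[w, ia], x[w, ib],
      B = cfg$bootstrap_iterations,
      seed = derive_seed(cfg$rng_seed, w),
      enumerate = cfg$enumerate
    )
  })
  p <- purrr::map_dbl(res, "p")
  new_detection_table(
    exp, ia, ib, method = "bootstrap_t",
    statistic = purrr::map_dbl(res, "t"),
    p_value = p, is_significant = p < cfg$alpha,
    group_a = group_a, group_b = group_b, cfg = cfg
  )
}
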