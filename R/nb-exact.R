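#' Estimate a common negative-binomial dispersion
#'
#' Method-of-moments estimate shared by all windows: per window, the
#' within-group sample variances are pooled across treatment groups and
#' compared with the pooled mean; under NB, `var = mu + phi * mu^2`, so
#' `phi_w = (s2_w - mu_w) / mu_w^2` (floored at 0). The common dispersion
#' is the median of the per-window values, which is robust to the minority
#' of genuinely differential windows. Requires replication in at least one
#' group; groups without replicates contribute nothing to the variance
#' pool.
#'
#' @param exp A `capwin_experiment`; the `"normalized"` layer is used when
#'   present.
#' @param groups Optional grouping vector over samples; defaults to the
#'   sample sheet's `treatment` column.
#' @return A single non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(exp, groups = NULL) {
  validate_experiment(exp)
  groups <- groups %||% exp$samples$treatment
  if (length(groups) != ncol(exp$counts)) {
    abort("`groups` must have one entry per sample")
  }
  m <- working_matrix(exp)
  glev <- unique(groups)
  sizes <- vapply(glev, function(g) sum(groups == g), integer(1))
  rep_groups <- glev[sizes >= 2]
  if (length(rep_groups) == 0) {
    abort(paste("no group has >= 2 replicates; supply `dispersion`",
                "explicitly in test_config()"))
  }
  ss <- matrix(0, nrow(m), 1)   # pooled sum of squares
  df <- 0
  mu_num <- rep(0, nrow(m)); mu_den <- 0
  for (g in rep_groups) {
    cols <- which(groups == g)
    sub <- m[, cols, drop = FALSE]
    mu_g <- rowMeans(sub)
    ss <- ss + rowSums((sub - mu_g)^2)
    df <- df + (length(cols) - 1)
    mu_num <- mu_num + mu_g * length(cols)
    mu_den <- mu_den + length(cols)
  }
  s2 <- as.vector(ss) / df
  mu <- mu_num / mu_den
  ok <- mu > 0
  if (!any(ok)) return(0)
  phi_w <- pmax(0, (s2[ok] - mu[ok]) / mu[ok]^2)
  median(phi_w)
}

#' Exact conditional NB p-value for one window
#'
#' Two-sided exact test for a difference between two groups of
#' negative-binomial counts with common dispersion `phi`, conditioning on
#' the window's total. With group sums `(ya, yb)` from `n_a` and `n_b`
#' samples at a common effective library size, the conditional null
#' distribution of `ya` given `ya + yb = t` follows from the group sums
#' being NB with sizes `n_a/phi` and `n_b/phi`. At `phi = 0` this is the
#' binomial `Bin(t, n_a/(n_a+n_b))` (the Poisson exact test), where the
#' two-sided p is the doubled smaller tail, capped at 1; for `phi > 0`
#' the two-sided p sums all conditional outcome probabilities no larger
#' than the observed one (minimum-likelihood rule, ties counted once).
#'
#' @param ya,yb Group sums (non-negative, rounded to integers).
#' @param n_a,n_b Group sizes.
#' @param phi Common NB dispersion (>= 0); 0 gives the Poisson case.
#' @return p-value in (0, 1].
#' @export
nb_exact_pvalue <- function(ya, yb, n_a, n_b, phi = 0) {
  if (!is.finite(phi) || phi < 0) abort("dispersion must be finite and >= 0")
  ya <- round(ya); yb <- round(yb)
  t <- ya + yb
  if (t == 0) return(1)
  if (phi == 0) {
    pr <- n_a / (n_a + n_b)
    lower <- pbinom(ya, t, pr)
    upper <- pbinom(ya - 1, t, pr, lower.tail = FALSE)
    return(min(1, 2 * min(lower, upper)))
  }
  k <- 0:t
  # conditional probabilities do not depend on the common mean m
  m <- max(t / (n_a + n_b), 1e-8)
  lp <- dnbinom(k, size = n_a / phi, mu = n_a * m, log = TRUE) +
    dnbinom(t - k, size = n_b / phi, mu = n_b * m, log = TRUE)
  lp <- lp - max(lp)
  p <- exp(lp)
  p <- p / sum(p)
  p_obs <- p[ya + 1]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Negative-binomial exact test across windows
#'
#' The classic exact-test route for count data, re-implemented as its
#' statistical core: a single common dispersion is estimated (or supplied)
#' and every window is tested with [nb_exact_pvalue()] on group sums of
#' the normalized counts. Counts should be normalized to a common
#' effective library size first (see [normalize_experiment()]); raw
#' counts are used as-is when no normalized layer exists.
#'
#' @param exp A `capwin_experiment`.
#' @param group_a,group_b Treatment labels of the two groups.
#' @param cfg A [test_config()]; `alpha` and `dispersion` are used.
#' @return A `capwin_detection` tibble, one row per window, with
#'   `p_value` and `is_significant` (`p < alpha`, strict).
#' @export
nb_exact_test <- function(exp, group_a, group_b, cfg = test_config()) {
  validate_experiment(exp)
  ia <- group_columns(exp, group_a)
  ib <- group_columns(exp, group_b)
  m <- working_matrix(exp)
  phi <- cfg$dispersion %||%
    estimate_common_dispersion(exp, groups = ifelse(
      seq_len(ncol(m)) %in% ia, "a", ifelse(seq_len(ncol(m)) %in% ib, "b", "other")
    ))
  ya <- rowSums(m[, ia, drop = FALSE])
  yb <- rowSums(m[, ib, drop = FALSE])
  p <- vapply(seq_len(nrow(m)), function(w) {
    nb_exact_pvalue(ya[w], yb[w], length(ia), length(ib), phi)
  }, numeric(1))
  new_detection_table(
    exp, ia, ib, method = "nb_exact", p_value = p,
    is_significant = p < cfg$alpha,
    group_a = group_a, group_b = group_b, cfg = cfg
  )
}
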