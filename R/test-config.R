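#' Configuration for differential tests
#'
#' Collects the knobs shared by the three detectors.
#'
#' @param alpha Significance level for the p-value based methods (strict:
#'   significant iff p < alpha). Default 0.05.
#' @param bf_threshold Bayes-factor calling threshold (significant iff
#'   BF10 >= threshold). Must exceed 1. Default 1.5.
#' @param bootstrap_iterations Number of bootstrap resamples B (>= 100).
#'   Default 1000.
#' @param rng_seed Integer seed for the bootstrap; per-window substreams
#'   are derived from it so results are reproducible regardless of
#'   evaluation order.
#' @param transform `"log2_pseudo"` (the t-based methods work on
#'   `log2(x + 0.5)` of the normalized counts) or `"none"`.
#' @param dispersion Optional fixed NB dispersion for the exact test; when
#'   `NULL` it is estimated with [estimate_common_dispersion()].
#' @param r_scale Cauchy prior scale of the JZS Bayes factor; default
#'   `sqrt(2)/2` (the conventional "medium" prior).
#' @param enumerate If `TRUE`, the bootstrap enumerates every within-group
#'   resample combination instead of sampling B of them; only feasible for
#'   tiny groups (the number of combinations is `n_a^n_a * n_b^n_b`).
#' @return A `capwin_test_config` list.
#' @export
test_config <- function(alpha = 0.05, bf_threshold = 1.5,
                        bootstrap_iterations = 1000, rng_seed = 42,
                        transform = c("log2_pseudo", "none"),
                        dispersion = NULL, r_scale = sqrt(2) / 2,
                        enumerate = FALSE) {
  assert_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  assert_number(bf_threshold, "bf_threshold", lower = 1 + 1e-12)
  assert_number(bootstrap_iterations, "bootstrap_iterations", lower = 100)
  assert_number(r_scale, "r_scale", lower = 1e-12)
  assert_flag(enumerate, "enumerate")
  if (!is.null(dispersion)) assert_number(dispersion, "dispersion", lower = 0)
  structure(
    list(alpha = alpha, bf_threshold = bf_threshold,
         bootstrap_iterations = as.integer(bootstrap_iterations),
         rng_seed = as.integer(rng_seed), transform = match.arg(transform),
         dispersion = dispersion, r_scale = r_scale, enumerate = enumerate),
    class = "capwin_test_config"
  )
}

# resolve treatment labels to column indices of the count matrix
group_columns <- function(exp, treatment) {
  idx <- which(exp$samples$treatment == treatment)
  if (length(idx) == 0) {
    abort(sprintf("no samples with treatment '%s'", treatment))
  }
  idx
}

transform_matrix <- function(m, transform) {
  if (transform == "log2_pseudo") log2(m + 0.5) else m
}

# assemble the per-window result tibble common to all three detectors
new_detection_table <- function(exp, ia, ib, method, statistic = NA_real_,
                                p_value = NA_real_, bayes_factor = NA_real_,
                                is_significant, group_a, group_b, cfg) {
  m <- working_matrix(exp)
  mean_a <- rowMeans(m[, ia, drop = FALSE])
  mean_b <- rowMeans(m[, ib, drop = FALSE])
  out <- tibble(
    window_id = rownames(m),
    mean_a = mean_a,
    mean_b = mean_b,
    log2_fc = log2((mean_b + 0.5) / (mean_a + 0.5)),
    statistic = statistic,
    p_value = p_value,
    bayes_factor = bayes_factor,
    is_significant = is_significant,
    method = method
  )
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "config") <- cfg
  class(out) <- c("capwin_detection", class(out))
  out
}

#' @method glance capwin_detection
#' @export
glance.capwin_detection <- function(x, ...) {
  tibble(
    method = x$method[1],
    group_a = attr(x, "group_a") %||% NA_character_,
    group_b = attr(x, "group_b") %||% NA_character_,
    n_windows = nrow(x),
    n_significant = sum(x$is_significant),
    prop_significant = mean(x$is_significant)
  )
}

#' @method tidy capwin_detection
#' @export
tidy.capwin_detection <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "capwin_detection")
  attr(out, "group_a") <- NULL
  attr(out, "group_b") <- NULL
  attr(out, "config") <- NULL
  out
}

#' Benjamini-Hochberg adjustment of a detection table
#'
#' Optional multiple-testing layer for the p-value based methods; the
#' significance flag is recomputed on the adjusted p-values. Not applied
#' anywhere by default: the benchmark and the detectors call windows on
#' raw p-values at a stated detection level.
#'
#' @param detections A `capwin_detection` from a p-value based method.
#' @param alpha Adjusted-p cutoff (strict).
#' @return The table with columns `p_adjusted` and updated
#'   `is_significant`.
#' @export
adjust_significance <- function(detections, alpha = 0.05) {
  if (all(is.na(detections$p_value))) {
    abort("no p-values to adjust (Bayes-factor tables have none)")
  }
  detections$p_adjusted <- p.adjust(detections$p_value, method = "BH")
  detections$is_significant <- detections$p_adjusted < alpha
  detections
}
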