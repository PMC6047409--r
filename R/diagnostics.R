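#' Per-sample summary of an enrichment experiment
#'
#' The first question after a capture experiment is whether reads actually
#' went on target. This table gives, per sample, the total window count,
#' the on-target count and fraction, mean and median window counts, and
#' the number of non-zero windows.
#'
#' @param exp A `capwin_experiment`.
#' @return A tibble with one row per sample.
#' @export
sample_summary <- function(exp) {
  validate_experiment(exp)
  m <- exp$counts
  on <- exp$windows$target_class == "on_target"
  totals <- colSums(m)
  on_tot <- if (any(on)) colSums(m[on, , drop = FALSE]) else rep(0, ncol(m))
  tibble(
    sample_id = exp$samples$sample_id,
    treatment = exp$samples$treatment,
    total_count = as.integer(unname(totals)),
    on_target_count = as.integer(unname(on_tot)),
    on_target_fraction = unname(ifelse(totals > 0, on_tot / totals, 0)),
    mean_count = unname(colMeans(m)),
    median_count = unname(apply(m, 2, median)),
    windows_nonzero = as.integer(colSums(m > 0))
  )
}

#' Per-window MA values against a reference sample
#'
#' M is the log2 ratio of a sample's count to the reference count, A the
#' mean log2 intensity; both use a pseudocount so windows with zeros stay
#' finite. These are the coordinates of the classic MA diagnostic plot.
#'
#' @param exp A `capwin_experiment`.
#' @param reference_sample `sample_id` of the reference column.
#' @param pseudocount Added to every count before taking logs; default 0.5.
#' @param layer Matrix to use (`"counts"` or a layer name).
#' @return A tibble with columns `window_id`, `sample_id`, `M`, `A` for
#'   every non-reference sample.
#' @export
ma_values <- function(exp, reference_sample, pseudocount = 0.5, layer = "counts") {
  validate_experiment(exp)
  assert_number(pseudocount, "pseudocount", lower = 0)
  m <- count_matrix(exp, layer)
  if (!reference_sample %in% colnames(m)) {
    abort(sprintf("reference sample '%s' not in experiment", reference_sample))
  }
  ref <- m[, reference_sample]
  others <- setdiff(colnames(m), reference_sample)
  if (length(others) == 0) others <- reference_sample
  purrr::map_dfr(others, function(s) {
    x <- m[, s]
    tibble(
      window_id = rownames(m),
      sample_id = s,
      M = unname(log2((x + pseudocount) / (ref + pseudocount))),
      A = unname(0.5 * log2((x + pseudocount) * (ref + pseudocount)))
    )
  })
}

#' Sample-sample similarity matrix
#'
#' Correlation between samples on log2(count + 1), the statistic behind a
#' sample similarity heat map. A sample with zero variance gets `NA`
#' against everything (with a warning) since correlation is undefined.
#'
#' @param exp A `capwin_experiment`.
#' @param method `"pearson"` or `"spearman"`.
#' @param layer Matrix to use.
#' @return Symmetric numeric matrix, samples by samples, unit diagonal.
#' @export
sample_similarity <- function(exp, method = c("pearson", "spearman"),
                              layer = "counts") {
  validate_experiment(exp)
  method <- match.arg(method)
  m <- count_matrix(exp, layer)
  if (ncol(m) < 2) abort("need at least 2 samples for a similarity matrix")
  lm2 <- log2(m + 1)
  flat <- col_vars(lm2) == 0
  if (any(flat)) {
    warn(sprintf("constant sample(s), similarity undefined: %s",
                 paste(colnames(m)[flat], collapse = ", ")))
  }
  out <- suppressWarnings(cor(lm2, method = method))
  out[flat, ] <- NA_real_
  out[, flat] <- NA_real_
  diag(out) <- 1
  out
}

#' Tidy per-window coverage table for density/histogram plots
#'
#' @param exp A `capwin_experiment`.
#' @param per Grouping intent recorded in the result ordering: `"sample"`
#'   or `"chromosome"`. No binning is applied; the table feeds ggplot2.
#' @param layer Matrix to use.
#' @return A tibble (sample_id, treatment, chrom, window_id, target_class,
#'   count), one row per window per sample.
#' @export
coverage_density <- function(exp, per = c("sample", "chromosome"),
                             layer = "counts") {
  validate_experiment(exp)
  per <- match.arg(per)
  long <- tidy(exp, layer = layer) |>
    select("sample_id", "treatment", "chrom", "window_id", "target_class", "count")
  if (per == "chromosome") arrange(long, .data$chrom, .data$sample_id)
  else arrange(long, .data$sample_id, .data$chrom)
}
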