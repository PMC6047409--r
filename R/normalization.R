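#' Normalization factor objects
#'
#' Per-sample positive scale factors plus provenance: the method that made
#' them and the windows they were estimated from. Counts are divided by
#' the factors, which are always geometric-mean-centred (their product is
#' 1), so normalization redistributes scale between samples without
#' changing the overall level.
#'
#' @param factors Named numeric vector, one positive factor per sample.
#' @param method One of `"library_size"`, `"gof"`, `"control_windows"`,
#'   `"custom"`.
#' @param windows_used Character vector of the window ids the factors were
#'   estimated from (empty for library_size/custom).
#' @param gof_quantile The selection quantile, for method `"gof"`.
#' @return A `capwin_norm_factors` object.
#' @export
new_norm_factors <- function(factors, method, windows_used = character(0),
                             gof_quantile = NULL) {
  if (any(!is.finite(factors) | factors <= 0)) {
    abort("normalization factors must be finite and > 0")
  }
  structure(
    list(factors = factors, method = method, windows_used = windows_used,
         gof_quantile = gof_quantile),
    class = "capwin_norm_factors"
  )
}

#' @export
print.capwin_norm_factors <- function(x, ...) {
  cat(sprintf("<capwin_norm_factors> method=%s, %d samples", x$method,
              length(x$factors)))
  if (length(x$windows_used) > 0) {
    cat(sprintf(", %d windows used", length(x$windows_used)))
  }
  cat("\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' @method tidy capwin_norm_factors
#' @export
tidy.capwin_norm_factors <- function(x, ...) {
  tibble(sample_id = names(x$factors), factor = unname(x$factors),
         method = x$method)
}

center_factors <- function(f) f / geometric_mean(f)

#' Library-size normalization factors
#'
#' Each sample's factor is its total count divided by the geometric mean of
#' all totals; dividing by the factor equalizes effective library sizes.
#' For capture data this is only sound when counts are reasonably high
#' (mean > 20) and few windows change between treatments; an advisory is
#' emitted when the mean-count heuristic is violated.
#'
#' @param exp A `capwin_experiment`.
#' @return A `capwin_norm_factors` with method `"library_size"`.
#' @export
library_size_factors <- function(exp) {
  validate_experiment(exp)
  totals <- colSums(exp$counts)
  if (any(totals == 0)) {
    abort(sprintf("sample(s) with zero total count: %s",
                  paste(colnames(exp$counts)[totals == 0], collapse = ", ")))
  }
  if (mean(exp$counts) <= 20) {
    inform(paste(
      "library-size normalization advisory: mean window count is <= 20;",
      "this method is only recommended for reasonably high counts (> 20 mean)",
      "and when < 10% of windows are expected to change"
    ))
  }
  new_norm_factors(center_factors(totals), "library_size")
}

#' Per-window goodness-of-fit statistics
#'
#' The goodness-of-fit (GoF) statistic measures how variable a window is
#' across samples after library-size scaling: for scaled counts `y_ws`
#' with window mean `mu_w`, `gof_w = sum_s (y_ws - mu_w)^2 / mu_w`, the
#' Pearson goodness-of-fit statistic. Windows with the lowest GoF are the
#' most stable and make the best normalization anchors. All-zero windows
#' get `Inf` and are never selected.
#'
#' @param exp A `capwin_experiment` with at least 2 samples.
#' @param quantile Optional selection quantile in (0, 1]; when given, the
#'   `selected` column marks windows with `gof <=` that quantile of the
#'   finite GoF distribution.
#' @return A tibble (window_id, target_class, gof, rank, selected) sorted
#'   in window order; rank 1 is the least variable window.
#' @export
gof_stats <- function(exp, quantile = NULL) {
  validate_experiment(exp)
  if (ncol(exp$counts) < 2) abort("GoF needs at least 2 samples")
  f <- library_size_scaling(exp)
  y <- sweep(exp$counts, 2, f, "/")
  mu <- rowMeans(y)
  gof <- ifelse(mu > 0, rowSums((y - mu)^2) / mu, Inf)
  sel <- rep(NA, length(gof))
  if (!is.null(quantile)) {
    assert_number(quantile, "quantile", lower = 0, upper = 1)
    fin <- is.finite(gof)
    if (!any(fin)) abort("no windows with finite GoF; cannot select")
    cut <- stats::quantile(gof[fin], quantile, names = FALSE)
    sel <- is.finite(gof) & gof <= cut
  }
  tibble(
    window_id = rownames(exp$counts),
    target_class = exp$windows$target_class,
    gof = unname(gof),
    rank = unname(rank(gof, ties.method = "first")),
    selected = sel
  )
}

# raw library-size factors without the advisory chatter (internal)
library_size_scaling <- function(exp) {
  totals <- colSums(exp$counts)
  if (any(totals == 0)) {
    abort(sprintf("sample(s) with zero total count: %s",
                  paste(colnames(exp$counts)[totals == 0], collapse = ", ")))
  }
  center_factors(totals)
}

# median-of-ratios factors over a window subset (DESeq-style geometric-mean
# reference); windows with any zero count carry an undefined reference and
# are dropped from the medians
median_of_ratios <- function(counts, window_ids) {
  sub <- counts[window_ids, , drop = FALSE]
  pos <- rowSums(sub > 0) == ncol(sub)
  if (!any(pos)) {
    abort("no usable windows (every candidate window has a zero count in some sample)")
  }
  sub <- sub[pos, , drop = FALSE]
  ref <- apply(sub, 1, geometric_mean)
  ratios <- sub / ref
  f <- apply(ratios, 2, median)
  center_factors(f)
}

#' Lowest-GoF normalization factors
#'
#' The dynamic method: compute per-window GoF, keep the fraction of
#' windows with the lowest GoF (the least variable windows, default the
#' lowest quarter), and estimate per-sample factors from that subset by
#' the median-of-ratios scheme against a geometric-mean reference. This
#' finds normalization anchors automatically and behaves the same whether
#' few or many windows are truly changing.
#'
#' @param exp A `capwin_experiment`.
#' @param quantile Fraction of finite-GoF windows to select, in (0, 1].
#'   Default 0.25.
#' @return A `capwin_norm_factors` with method `"gof"` and the selected
#'   window ids in `windows_used`.
#' @export
gof_factors <- function(exp, quantile = 0.25) {
  validate_experiment(exp)
  gt <- gof_stats(exp, quantile = quantile)
  used <- gt$window_id[gt$selected]
  if (length(used) < 2) abort("fewer than 2 windows selectable by GoF")
  f <- median_of_ratios(exp$counts, used)
  new_norm_factors(f, "gof", windows_used = used, gof_quantile = quantile)
}

#' Control-window normalization factors
#'
#' Factors estimated, as in [gof_factors()], by median-of-ratios but over
#' windows the user nominates as unchanging (control regions), instead of
#' windows selected by the data.
#'
#' @param exp A `capwin_experiment`.
#' @param controls Character window ids, a window-set tibble, or a path to
#'   a BED4 / one-id-per-line file. If omitted, windows already flagged
#'   `target_class == "control"` in the experiment are used.
#' @return A `capwin_norm_factors` with method `"control_windows"`.
#' @export
control_window_factors <- function(exp, controls = NULL) {
  validate_experiment(exp)
  if (is.null(controls)) {
    ids <- exp$windows$window_id[exp$windows$target_class == "control"]
    if (length(ids) == 0) abort("experiment has no windows with target_class 'control'")
  } else {
    ctrl <- resolve_controls(controls)
    ids <- if (is.character(ctrl)) ctrl else ctrl$window_id
    missed <- setdiff(ids, exp$windows$window_id)
    if (length(missed) > 0) {
      abort(sprintf("control window(s) not in experiment: %s",
                    paste(missed, collapse = ", ")))
    }
  }
  f <- median_of_ratios(exp$counts, ids)
  new_norm_factors(f, "control_windows", windows_used = ids)
}

#' Custom normalization factors
#'
#' Accepts factors computed elsewhere, as a named numeric vector or a CSV
#' file with columns `sample_id,factor`. Factors are geometric-mean
#' centred so their product is 1, like every other method.
#'
#' @param exp A `capwin_experiment`.
#' @param factors Named numeric vector (names = sample ids) or CSV path.
#' @return A `capwin_norm_factors` with method `"custom"`.
#' @export
custom_factors <- function(exp, factors) {
  validate_experiment(exp)
  if (is.character(factors) && length(factors) == 1) {
    tab <- readr::read_csv(factors, show_col_types = FALSE, progress = FALSE)
    if (!all(c("sample_id", "factor") %in% names(tab))) {
      abort("custom factor CSV must have columns sample_id,factor")
    }
    factors <- setNames(tab$factor, tab$sample_id)
  }
  ids <- colnames(exp$counts)
  if (is.null(names(factors)) || !setequal(names(factors), ids)) {
    abort("custom factors must be named with exactly the experiment's sample ids")
  }
  f <- factors[ids]
  if (any(!is.finite(f) | f <= 0)) abort("custom factors must be finite and > 0")
  new_norm_factors(center_factors(f), "custom")
}

#' Apply normalization factors to an experiment
#'
#' Adds (or, with a warning, replaces) the `"normalized"` layer holding
#' `count / factor` per sample; raw counts are untouched and the factor
#' object is recorded on the experiment.
#'
#' @param exp A `capwin_experiment`.
#' @param nf A `capwin_norm_factors` whose samples match the experiment.
#' @return The experiment with a `"normalized"` layer and `norm_factors`
#'   set.
#' @export
apply_factors <- function(exp, nf) {
  validate_experiment(exp)
  if (!inherits(nf, "capwin_norm_factors")) abort("nf must be a capwin_norm_factors")
  ids <- colnames(exp$counts)
  if (length(nf$factors) != length(ids) || !setequal(names(nf$factors), ids)) {
    abort("factor names do not match the experiment's samples")
  }
  if ("normalized" %in% names(exp$layers)) {
    warn("overwriting existing 'normalized' layer")
  }
  exp$layers[["normalized"]] <- sweep(exp$counts, 2, nf$factors[ids], "/")
  exp$norm_factors <- nf
  exp
}

#' Normalize in one call
#'
#' Convenience wrapper: estimate factors by the chosen method and apply
#' them.
#'
#' @param exp A `capwin_experiment`.
#' @param method `"gof"`, `"library_size"`, `"control_windows"` or
#'   `"custom"`.
#' @param ... Passed to the factor estimator (`quantile`, `controls`,
#'   `factors`).
#' @return The experiment with a `"normalized"` layer.
#' @export
normalize_experiment <- function(exp, method = c("gof", "library_size",
                                                 "control_windows", "custom"),
                                 ...) {
  method <- match.arg(method)
  nf <- switch(method,
    gof = gof_factors(exp, ...),
    library_size = library_size_factors(exp),
    control_windows = control_window_factors(exp, ...),
    custom = custom_factors(exp, ...)
  )
  apply_factors(exp, nf)
}
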