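#' Construct a capwin experiment
#'
#' The central container: an ordered window set, an ordered sample sheet,
#' a window-by-sample matrix of non-negative integer counts, and any
#' number of named derived layers (e.g. `"normalized"`) of identical
#' shape. It is a plain R list with class `capwin_experiment`, so derived
#' data can ride along without ceremony.
#'
#' @param windows Window set tibble (`chrom`, `start`, `end`, `window_id`,
#'   `target_class`).
#' @param samples Sample sheet tibble (`sample_id`, `treatment`,
#'   `replicate`, optionally `bam_path`).
#' @param counts Matrix of non-negative counts, rows in window order,
#'   columns in sample order.
#' @param layers Named list of numeric matrices with the same shape and
#'   dimnames as `counts`.
#' @param norm_factors Optional `capwin_norm_factors` object.
#' @return A `capwin_experiment`.
#' @export
new_experiment <- function(windows, samples, counts, layers = list(),
                           norm_factors = NULL) {
  validate_windows(windows)
  validate_samples(samples)
  if (!("target_class" %in% names(windows))) windows$target_class <- "on_target"
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(windows) || ncol(counts) != nrow(samples)) {
    abort(sprintf(
      "counts is %d x %d but there are %d windows and %d samples",
      nrow(counts), ncol(counts), nrow(windows), nrow(samples)
    ))
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("counts must be finite and non-negative")
  }
  dimnames(counts) <- list(windows$window_id, samples$sample_id)
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!is.matrix(l) || !all(dim(l) == dim(counts))) {
      abort(sprintf("layer '%s' does not match the count matrix shape", nm))
    }
    dimnames(layers[[nm]]) <- dimnames(counts)
  }
  structure(
    list(windows = as_tibble(windows), samples = as_tibble(samples),
         counts = counts, layers = layers, norm_factors = norm_factors),
    class = "capwin_experiment"
  )
}

validate_experiment <- function(exp) {
  if (!inherits(exp, "capwin_experiment")) {
    abort("expected a capwin_experiment (see build_experiment())")
  }
  invisible(exp)
}

#' @export
print.capwin_experiment <- function(x, ...) {
  cat(sprintf(
    "<capwin_experiment> %d windows x %d samples\n",
    nrow(x$windows), nrow(x$samples)
  ))
  cls <- table(x$windows$target_class)
  cat("  windows:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  cat("  treatments:", paste(unique(x$samples$treatment), collapse = ", "), "\n")
  if (length(x$layers) > 0) {
    cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  }
  if (!is.null(x$norm_factors)) {
    cat("  normalized by:", x$norm_factors$method, "\n")
  }
  invisible(x)
}

#' Extract a count or layer matrix
#'
#' @param exp A `capwin_experiment`.
#' @param layer `"counts"` for the raw counts, or the name of a derived
#'   layer such as `"normalized"`.
#' @return Numeric matrix, windows by samples.
#' @export
count_matrix <- function(exp, layer = "counts") {
  validate_experiment(exp)
  if (layer == "counts") return(exp$counts)
  if (!layer %in% names(exp$layers)) {
    abort(sprintf("layer '%s' not found (available: %s)", layer,
                  paste(c("counts", names(exp$layers)), collapse = ", ")))
  }
  exp$layers[[layer]]
}

# normalized layer if present, else raw counts
working_matrix <- function(exp) {
  if ("normalized" %in% names(exp$layers)) exp$layers[["normalized"]] else exp$counts
}

#' Subset an experiment by target class
#'
#' Every analysis function can be pointed at the on-target, off-target or
#' control windows via this operation; `by = "all"` returns an equivalent
#' copy.
#'
#' @param exp A `capwin_experiment`.
#' @param by One of `"all"`, `"on_target"`, `"off_target"`, `"control"`.
#' @return A `capwin_experiment` restricted to the chosen class, with all
#'   layers subset identically.
#' @export
subset_by <- function(exp, by = c("all", "on_target", "off_target", "control")) {
  validate_experiment(exp)
  by <- match.arg(by)
  if (by == "all") keep <- rep(TRUE, nrow(exp$windows))
  else keep <- exp$windows$target_class == by
  if (!any(keep)) abort(sprintf("no windows with target_class '%s'", by))
  new_experiment(
    windows = exp$windows[keep, , drop = FALSE],
    samples = exp$samples,
    counts = exp$counts[keep, , drop = FALSE],
    layers = lapply(exp$layers, function(l) l[keep, , drop = FALSE]),
    norm_factors = exp$norm_factors
  )
}

#' Tidy an experiment into long format
#'
#' @param x A `capwin_experiment`.
#' @param layer Which matrix to tidy (`"counts"` or a layer name).
#' @param ... Unused.
#' @return A tibble with one row per window x sample: window annotation,
#'   sample annotation, and `count`.
#' @method tidy capwin_experiment
#' @export
tidy.capwin_experiment <- function(x, layer = "counts", ...) {
  m <- count_matrix(x, layer)
  long <- as_tibble(m, rownames = "window_id") |>
    tidyr::pivot_longer(-"window_id", names_to = "sample_id", values_to = "count")
  long |>
    left_join(x$windows, by = "window_id") |>
    left_join(x$samples[, intersect(names(x$samples),
                                    c("sample_id", "treatment", "replicate"))],
              by = "sample_id") |>
    select("window_id", "chrom", "start", "end", "target_class",
           "sample_id", "treatment", "replicate", "count")
}

#' One-line experiment overview
#'
#' @param x A `capwin_experiment`.
#' @param ... Unused.
#' @return A one-row tibble: window/sample/treatment tallies, total count,
#'   normalization method if applied.
#' @method glance capwin_experiment
#' @export
glance.capwin_experiment <- function(x, ...) {
  tibble(
    n_windows = nrow(x$windows),
    n_samples = nrow(x$samples),
    n_treatments = length(unique(x$samples$treatment)),
    n_on_target = sum(x$windows$target_class == "on_target"),
    n_control = sum(x$windows$target_class == "control"),
    total_count = sum(x$counts),
    norm_method = if (is.null(x$norm_factors)) NA_character_ else x$norm_factors$method
  )
}

#' Write and read a count matrix as TSV
#'
#' The TSV has `window_id` as the first column and one column per sample,
#' so experiments move between pipeline steps as plain text.
#'
#' @param exp A `capwin_experiment`.
#' @param path Output path.
#' @param layer Which matrix to write.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(exp, path, layer = "counts") {
  m <- count_matrix(exp, layer)
  readr::write_tsv(as_tibble(m, rownames = "window_id"), path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param windows,samples Window set and sample sheet to attach; windows
#'   may be `NULL`, in which case nominal single-chromosome windows are
#'   created from the row order.
#' @export
read_counts_tsv <- function(path, windows = NULL, samples = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"window_id" %in% names(tab)) abort("count TSV must have a window_id column")
  m <- as.matrix(tab[, setdiff(names(tab), "window_id")])
  rownames(m) <- tab$window_id
  if (is.null(windows)) {
    windows <- tibble(
      chrom = "unplaced",
      start = (seq_len(nrow(m)) - 1L) * 100L,
      end = seq_len(nrow(m)) * 100L,
      window_id = rownames(m),
      target_class = "on_target"
    )
  } else {
    validate_windows(windows)
    windows <- windows[match(rownames(m), windows$window_id), , drop = FALSE]
    if (anyNA(windows$window_id)) abort("count TSV contains windows absent from the window set")
  }
  if (is.null(samples)) {
    samples <- tibble(
      sample_id = colnames(m),
      treatment = colnames(m),
      replicate = 1L
    )
  } else {
    validate_samples(samples)
    samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
    if (anyNA(samples$sample_id)) abort("count TSV contains samples absent from the sample sheet")
  }
  new_experiment(windows, samples, m)
}
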