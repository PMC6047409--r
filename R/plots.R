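#' Diagnostic plot builders
#'
#' Each `plot_*` function is a thin ggplot2 layer over the corresponding
#' statistics table, so everything plotted is separately testable as a
#' tibble.
#'
#' @param exp A `capwin_experiment`.
#' @param layer Which matrix to plot.
#' @return A ggplot object.
#' @name capwin-plots
NULL

#' @rdname capwin-plots
#' @export
plot_coverage_density <- function(exp, layer = "counts") {
  dat <- coverage_density(exp, layer = layer)
  ggplot2::ggplot(dat, ggplot2::aes(x = log2(.data$count + 1),
                                    colour = .data$sample_id)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "log2(count + 1)", y = "density",
                  title = "Per-sample coverage count density") +
    ggplot2::theme_minimal()
}

#' @rdname capwin-plots
#' @export
plot_chromosome_coverage <- function(exp, layer = "counts") {
  dat <- coverage_density(exp, per = "chromosome", layer = layer)
  ggplot2::ggplot(dat, ggplot2::aes(x = log2(.data$count + 1))) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_grid(chrom ~ sample_id) +
    ggplot2::labs(x = "log2(count + 1)", y = "windows",
                  title = "Per-chromosome coverage histogram") +
    ggplot2::theme_minimal()
}

#' @rdname capwin-plots
#' @param reference_sample Reference for the MA plot; default the first
#'   sample.
#' @param pseudocount Pseudocount for the log ratios.
#' @export
plot_ma <- function(exp, reference_sample = NULL, pseudocount = 0.5,
                    layer = "counts") {
  reference_sample <- reference_sample %||% exp$samples$sample_id[1]
  dat <- ma_values(exp, reference_sample, pseudocount = pseudocount,
                   layer = layer)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(title = sprintf("MA vs reference %s", reference_sample)) +
    ggplot2::theme_minimal()
}

#' @rdname capwin-plots
#' @param method Correlation method for the similarity heat map.
#' @export
plot_similarity_heatmap <- function(exp, method = "pearson", layer = "counts") {
  m <- sample_similarity(exp, method = method, layer = layer)
  dat <- as_tibble(m, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "correlation")
  ggplot2::ggplot(dat, ggplot2::aes(.data$sample_a, .data$sample_b,
                                    fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(dat$correlation, na.rm = TRUE), 1)) +
    ggplot2::labs(title = sprintf("Sample similarity (%s on log2 counts)", method),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname capwin-plots
#' @export
plot_target_density <- function(exp, layer = "counts") {
  dat <- coverage_density(exp, layer = layer)
  ggplot2::ggplot(dat, ggplot2::aes(x = log2(.data$count + 1),
                                    colour = .data$target_class)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = "log2(count + 1)", y = "density",
                  title = "On/off-target count density") +
    ggplot2::theme_minimal()
}

#' @rdname capwin-plots
#' @export
plot_gof_density <- function(exp) {
  gt <- gof_stats(exp)
  gt$group <- ifelse(gt$target_class == "control", "control", "non-control")
  fin <- gt[is.finite(gt$gof), ]
  ggplot2::ggplot(fin, ggplot2::aes(x = log10(.data$gof + 1e-6),
                                    colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "log10 GoF", y = "density",
                  title = "Goodness-of-fit density") +
    ggplot2::theme_minimal()
}

#' Render the standard diagnostic plot set to files
#'
#' Writes five PNGs to `outdir` (overwriting existing files of the same
#' name): coverage density, MA, similarity heat map, on/off-target
#' density, and GoF density. When the experiment has no control windows
#' the GoF density is simply drawn over all windows.
#'
#' @param exp A `capwin_experiment`.
#' @param outdir Writable output directory (created if needed).
#' @param width,height Device size in inches.
#' @return Character vector of the files written.
#' @export
render_plots <- function(exp, outdir, width = 7, height = 5) {
  validate_experiment(exp)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create output dir %s", outdir))
  plots <- list(
    coverage_density = plot_coverage_density(exp),
    ma = plot_ma(exp),
    similarity = plot_similarity_heatmap(exp),
    target_density = plot_target_density(exp),
    gof_density = plot_gof_density(exp)
  )
  files <- file.path(outdir, paste0(names(plots), ".png"))
  for (i in seq_along(plots)) {
    ggplot2::ggsave(files[i], plots[[i]], width = width, height = height,
                    dpi = 120)
  }
  files
}

#' Plot a detection table
#'
#' MA-style view: log2 fold change against mean abundance, significant
#' windows highlighted.
#'
#' @param object A `capwin_detection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot capwin_detection
#' @export
autoplot.capwin_detection <- function(object, ...) {
  dat <- tidy(object) |>
    mutate(mean_abundance = log2((.data$mean_a + .data$mean_b) / 2 + 0.5))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_abundance, y = .data$log2_fc,
                                    colour = .data$is_significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 mean abundance", y = "log2 fold change",
                  title = sprintf("Differential windows (%s)", object$method[1])) +
    ggplot2::theme_minimal()
}

#' Heat map of a benchmark summary
#'
#' Mean F (or precision/recall) as tiles over replicates and number of
#' changed windows, faceted by method and detection level — the standard
#' way to compare the detectors' operating characteristics.
#'
#' @param object A `capwin_benchmark_summary` from [summarize_grid()].
#' @param metric `"mean_f"`, `"mean_precision"` or `"mean_recall"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot capwin_benchmark_summary
#' @export
autoplot.capwin_benchmark_summary <- function(object, metric = "mean_f", ...) {
  if (!metric %in% names(object)) abort(sprintf("unknown metric '%s'", metric))
  dat <- object |>
    mutate(across(c("replicates", "n_changed", "fold_change"), factor))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_changed, y = .data$replicates,
                                    fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(fold_change ~ method + alpha,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = "windows changed", y = "replicates per treatment",
                  fill = metric) +
    ggplot2::theme_minimal()
}
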