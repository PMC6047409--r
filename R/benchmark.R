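#' Score a set of detection calls against the simulation truth
#'
#' @param truth Character vector of truly changed window ids.
#' @param calls Character vector of window ids called significant.
#' @return A one-row tibble with `TP`, `FP`, `FN`: TP are truly changed
#'   windows that were called, FP are calls that were not set as changed,
#'   FN are changed windows that were missed.
#' @export
score_calls <- function(truth, calls) {
  truth <- unique(truth); calls <- unique(calls)
  tibble(
    TP = length(intersect(truth, calls)),
    FP = length(setdiff(calls, truth)),
    FN = length(setdiff(truth, calls))
  )
}

#' Precision, recall and F from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(FN+TP)`,
#' `F = 2 * precision * recall / (precision + recall)`. Any 0/0 is
#' returned as `NA` (undefined) and later excluded from grid means.
#'
#' @param confusion A data frame with columns `TP`, `FP`, `FN` (any other
#'   columns pass through).
#' @return The input with `precision`, `recall`, `f_score` columns added.
#' @export
#' @examples
#' precision_recall_f(data.frame(TP = 3, FP = 1, FN = 2))
precision_recall_f <- function(confusion) {
  need <- c("TP", "FP", "FN")
  if (!is.data.frame(confusion) || !all(need %in% names(confusion))) {
    abort("confusion must be a data frame with columns TP, FP, FN")
  }
  confusion |>
    as_tibble() |>
    mutate(
      precision = ifelse(.data$TP + .data$FP > 0, .data$TP / (.data$TP + .data$FP), NA_real_),
      recall = ifelse(.data$FN + .data$TP > 0, .data$TP / (.data$FN + .data$TP), NA_real_),
      f_score = ifelse(
        !is.na(.data$precision) & !is.na(.data$recall) &
          (.data$precision + .data$recall) > 0,
        2 * .data$precision * .data$recall / (.data$precision + .data$recall),
        ifelse(!is.na(.data$precision) & !is.na(.data$recall), 0, NA_real_)
      )
    )
}

# default benchmark pairing of detection level with BF threshold
default_threshold_pairs <- function() {
  tibble(alpha = c(0.1, 0.05, 0.01), bf_threshold = c(1.1, 1.5, 2))
}

#' Run the detector benchmark over a parameter grid
#'
#' For every combination of replicates, number of changed windows, fold
#' change and detection threshold, and for each iteration: simulate an
#' experiment, run all three detectors, and score calls against the
#' simulation truth. The p-value methods call at `p < alpha`; the
#' Bayes-factor method calls at the paired `bf_threshold` (defaults:
#' alpha 0.1/0.05/0.01 paired with BF 1.1/1.5/2). Per-cell seeds are
#' derived deterministically from `seed`, the combination index and the
#' iteration, so the whole grid is reproducible.
#'
#' @param replicates,n_changed,fold_change Parameter vectors defining the
#'   grid (defaults: the benchmark design `{3,5,10}`, `{5,10,20}`,
#'   `{1.5,2,4}`).
#' @param thresholds Tibble with columns `alpha` and `bf_threshold`,
#'   paired row-wise; default [default_threshold_pairs()].
#' @param iterations Simulation repetitions per combination (default 10).
#' @param seed Master seed.
#' @param n_windows Windows per simulated experiment (default 52).
#' @param noise_cv Per-count noise level (default 0.1).
#' @param base_counts Optional base-count pool.
#' @param bootstrap_iters Bootstrap resamples for the bootstrap t method.
#' @param methods Which detectors to run.
#' @return A `capwin_benchmark` tibble: one row per method x combination
#'   x iteration with confusion counts and precision/recall/F.
#' @export
run_grid <- function(replicates = c(3, 5, 10), n_changed = c(5, 10, 20),
                     fold_change = c(1.5, 2, 4),
                     thresholds = default_threshold_pairs(),
                     iterations = 10, seed = 42, n_windows = 52,
                     noise_cv = 0.1, base_counts = NULL,
                     bootstrap_iters = 1000,
                     methods = c("nb_exact", "bootstrap_t", "bayes_factor")) {
  thresholds <- as_tibble(thresholds)
  if (!all(c("alpha", "bf_threshold") %in% names(thresholds))) {
    abort("thresholds must have columns alpha and bf_threshold")
  }
  methods <- match.arg(methods, several.ok = TRUE)
  combos <- tidyr::expand_grid(
    replicates = replicates, n_changed = n_changed,
    fold_change = fold_change, threshold = seq_len(nrow(thresholds))
  )
  if (nrow(combos) == 0) abort("empty parameter grid")

  rows <- purrr::map(seq_len(nrow(combos)), function(ci) {
    cc <- combos[ci, ]
    alpha <- thresholds$alpha[cc$threshold]
    bft <- thresholds$bf_threshold[cc$threshold]
    purrr::map(seq_len(iterations), function(it) {
      cell_seed <- derive_seed(seed, ci, it)
      sim <- simulate_experiment(simulation_spec(
        n_windows = n_windows, replicates = cc$replicates,
        n_changed = cc$n_changed, fold_change = cc$fold_change,
        noise_cv = noise_cv, base_counts = base_counts,
        rng_seed = cell_seed
      ))
      cfg <- test_config(
        alpha = alpha, bf_threshold = bft,
        bootstrap_iterations = bootstrap_iters,
        rng_seed = derive_seed(cell_seed, 1)
      )
      purrr::map(methods, function(m) {
        conf <- tryCatch({
          det <- detect_windows(sim$experiment, "control", "treatment",
                                method = m, cfg = cfg)
          score_calls(sim$truth, det$window_id[det$is_significant])
        }, error = function(e) {
          warn(sprintf("benchmark cell failed (method=%s, combo=%d, iter=%d): %s",
                       m, ci, it, conditionMessage(e)))
          tibble(TP = NA_integer_, FP = NA_integer_, FN = NA_integer_)
        })
        bind_cols(
          tibble(method = m, replicates = cc$replicates,
                 n_changed = cc$n_changed, fold_change = cc$fold_change,
                 alpha = alpha, bf_threshold = bft, iteration = it,
                 failed = anyNA(conf)),
          conf
        )
      }) |> bind_rows()
    }) |> bind_rows()
  }) |> bind_rows()

  out <- precision_recall_f(rows)
  class(out) <- c("capwin_benchmark", class(out))
  attr(out, "seed") <- seed
  out
}

#' Mean precision/recall/F per grid cell
#'
#' Arithmetic means over iterations, excluding undefined (`NA`) values —
#' an iteration where a method makes no calls at all has undefined
#' precision and simply does not contribute to that mean.
#'
#' @param grid A `capwin_benchmark` from [run_grid()].
#' @return A `capwin_benchmark_summary` tibble: one row per method x
#'   combination with `mean_precision`, `mean_recall`, `mean_f` and the
#'   number of iterations contributing to each.
#' @export
summarize_grid <- function(grid) {
  if (!is.data.frame(grid) || nrow(grid) == 0) abort("empty benchmark grid")
  out <- grid |>
    filter(!.data$failed) |>
    group_by(.data$method, .data$replicates, .data$n_changed,
             .data$fold_change, .data$alpha, .data$bf_threshold) |>
    summarise(
      iterations = n(),
      mean_precision = if (all(is.na(.data$precision))) NA_real_
                       else mean(.data$precision, na.rm = TRUE),
      mean_recall = if (all(is.na(.data$recall))) NA_real_
                    else mean(.data$recall, na.rm = TRUE),
      mean_f = if (all(is.na(.data$f_score))) NA_real_
               else mean(.data$f_score, na.rm = TRUE),
      .groups = "drop"
    )
  class(out) <- c("capwin_benchmark_summary", class(out))
  out
}

#' Which method wins where?
#'
#' Convenience view of a benchmark summary: the method with the highest
#' mean F per (replicates, n_changed, fold_change, alpha) cell, plus mean
#' F per method at each number of changed windows — the lens through
#' which overall detection power is usually compared.
#'
#' @param summary A `capwin_benchmark_summary`.
#' @return A list with `by_cell` (winning method per cell) and
#'   `by_n_changed` (mean F per method and n_changed).
#' @export
benchmark_verdict <- function(summary) {
  by_cell <- summary |>
    filter(!is.na(.data$mean_f)) |>
    group_by(.data$replicates, .data$n_changed, .data$fold_change, .data$alpha) |>
    filter(.data$mean_f == max(.data$mean_f)) |>
    ungroup() |>
    select("replicates", "n_changed", "fold_change", "alpha",
           best_method = "method", best_mean_f = "mean_f")
  by_n_changed <- summary |>
    group_by(.data$method, .data$n_changed) |>
    summarise(mean_f = mean(.data$mean_f, na.rm = TRUE), .groups = "drop") |>
    arrange(.data$n_changed, dplyr::desc(.data$mean_f))
  list(by_cell = by_cell, by_n_changed = by_n_changed)
}
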