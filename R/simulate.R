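# run code with a private RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Built-in base-count pool
#'
#' A fixed pool of 156 per-window base counts used as the sampling source
#' for simulated capture experiments. It is a synthetic stand-in, drawn
#' once from an equal-weight two-component lognormal mixture with modes
#' near 50 and 1000, reproducing the double-peaked count distribution
#' characteristic of target-enriched count data (a minority of windows
#' capture most of the reads). Shipped as a static file so simulations
#' are reproducible; substitute counts from a real pilot experiment via
#' the `source`/`base_counts` arguments where available.
#'
#' @return Numeric vector of 156 positive counts.
#' @export
builtin_base_counts <- function() {
  path <- system.file("extdata", "synthetic_base_counts.csv", package = "capwin")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)$count
}

#' Draw base counts for simulated windows
#'
#' @param n Number of windows to draw for.
#' @param source Pool of positive counts to draw from; default the
#'   built-in 156-value pool ([builtin_base_counts()]).
#' @param seed Optional seed; when given, the draw is made in a private
#'   RNG stream and is reproducible.
#' @return `n` values drawn uniformly with replacement from `source`.
#' @export
sample_base_counts <- function(n, source = NULL, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n <= 0) {
    abort("`n` must be a positive integer")
  }
  source <- source %||% builtin_base_counts()
  if (length(source) == 0 || any(!is.finite(source) | source <= 0)) {
    abort("`source` must be a non-empty vector of positive counts")
  }
  draw <- function() source[sample.int(length(source), n, replace = TRUE)]
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Specification of a simulated capture experiment
#'
#' Defaults mirror the benchmark's study design: 52 windows per arm, base
#' counts from the double-peaked pool, a chosen number of windows
#' multiplied by a fold change in every treatment replicate, and
#' per-count Gaussian noise with standard deviation proportional to the
#' expected count.
#'
#' @param n_windows Number of windows (default 52).
#' @param replicates Replicates per treatment arm.
#' @param n_changed Number of windows given a true fold change.
#' @param fold_change Multiplier (>= 1 for the benchmark; < 1 simulates
#'   loss of accessibility) applied to changed windows in the treatment
#'   arm.
#' @param noise_cv Coefficient of variation of the additive Gaussian
#'   noise: each realized count is
#'   `round(max(0, expected + N(0, noise_cv * expected)))`. Default 0.1.
#' @param base_counts Optional count pool; default
#'   [builtin_base_counts()].
#' @param rng_seed Integer seed; the whole simulation is deterministic
#'   given the spec.
#' @return A `capwin_sim_spec` list.
#' @export
simulation_spec <- function(n_windows = 52, replicates = 3, n_changed = 10,
                            fold_change = 2, noise_cv = 0.1,
                            base_counts = NULL, rng_seed = 42) {
  assert_number(n_windows, "n_windows", lower = 1)
  assert_number(replicates, "replicates", lower = 1)
  assert_number(n_changed, "n_changed", lower = 0)
  assert_number(fold_change, "fold_change", lower = 1e-9)
  assert_number(noise_cv, "noise_cv", lower = 0)
  if (n_changed > n_windows) {
    abort("n_changed cannot exceed n_windows")
  }
  structure(
    list(n_windows = as.integer(n_windows), replicates = as.integer(replicates),
         n_changed = as.integer(n_changed), fold_change = fold_change,
         noise_cv = noise_cv, base_counts = base_counts,
         rng_seed = as.integer(rng_seed)),
    class = "capwin_sim_spec"
  )
}

#' Simulate a control-vs-treatment capture experiment
#'
#' Windows get base counts drawn from the count pool; a random subset of
#' `n_changed` windows (the truth set) has its treatment-arm expectation
#' multiplied by `fold_change` in all replicates; every realized count in
#' both arms then receives rounded Gaussian noise with sd
#' `noise_cv * expected`, floored at zero. All windows are flagged
#' on-target. Deterministic given the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `experiment` (a `capwin_experiment`) and `truth`
#'   (character vector of truly changed window ids).
#' @export
simulate_experiment <- function(spec = simulation_spec()) {
  if (!inherits(spec, "capwin_sim_spec")) {
    abort("spec must come from simulation_spec()")
  }
  with_seed(spec$rng_seed, {
    ids <- sprintf("w%03d", seq_len(spec$n_windows))
    base <- sample_base_counts(spec$n_windows, source = spec$base_counts)
    truth <- if (spec$n_changed > 0) sample(ids, spec$n_changed) else character(0)

    expected <- cbind(
      matrix(base, spec$n_windows, spec$replicates),
      matrix(base * ifelse(ids %in% truth, spec$fold_change, 1),
             spec$n_windows, spec$replicates)
    )
    noise <- matrix(
      rnorm(length(expected), mean = 0, sd = spec$noise_cv * as.vector(expected)),
      nrow = spec$n_windows
    )
    counts <- round(pmax(expected + noise, 0))

    windows <- tibble(
      chrom = "sim",
      start = (seq_len(spec$n_windows) - 1L) * 1000L,
      end = seq_len(spec$n_windows) * 1000L,
      window_id = ids,
      target_class = "on_target"
    )
    samples <- tibble(
      sample_id = c(sprintf("control_%d", seq_len(spec$replicates)),
                    sprintf("treatment_%d", seq_len(spec$replicates))),
      treatment = rep(c("control", "treatment"), each = spec$replicates),
      replicate = rep(seq_len(spec$replicates), 2),
      bam_path = NA_character_
    )
    list(experiment = new_experiment(windows, samples, counts), truth = truth)
  })
}
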