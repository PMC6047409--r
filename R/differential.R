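#' Detect differential windows by any method
#'
#' Dispatcher over the three detectors, so pipelines can switch method by
#' name.
#'
#' @param exp A `capwin_experiment`.
#' @param group_a,group_b Treatment labels.
#' @param method `"nb_exact"`, `"bootstrap_t"` or `"bayes_factor"`.
#' @param cfg A [test_config()].
#' @return A `capwin_detection` tibble.
#' @export
detect_windows <- function(exp, group_a, group_b,
                           method = c("nb_exact", "bootstrap_t", "bayes_factor"),
                           cfg = test_config()) {
  method <- match.arg(method)
  switch(method,
    nb_exact = nb_exact_test(exp, group_a, group_b, cfg),
    bootstrap_t = bootstrap_t_test(exp, group_a, group_b, cfg),
    bayes_factor = bayes_factor_t_test(exp, group_a, group_b, cfg)
  )
}

#' Compare every treatment against a common reference
#'
#' Runs the chosen detector for each non-reference treatment against the
#' reference, with the same configuration throughout. Results are
#' identical to calling the pairwise test per treatment.
#'
#' @param exp A `capwin_experiment`.
#' @param reference_treatment Treatment used as `group_a` in every
#'   comparison.
#' @param method,cfg As in [detect_windows()].
#' @return A named list of `capwin_detection` tibbles, one per
#'   non-reference treatment.
#' @export
compare_to_reference <- function(exp, reference_treatment,
                                 method = c("nb_exact", "bootstrap_t", "bayes_factor"),
                                 cfg = test_config()) {
  validate_experiment(exp)
  method <- match.arg(method)
  treatments <- unique(exp$samples$treatment)
  if (!reference_treatment %in% treatments) {
    abort(sprintf("reference treatment '%s' not found", reference_treatment))
  }
  others <- setdiff(treatments, reference_treatment)
  if (length(others) == 0) {
    abort("no non-reference treatments to compare against")
  }
  out <- purrr::map(others, function(tr) {
    detect_windows(exp, reference_treatment, tr, method = method, cfg = cfg)
  })
  setNames(out, others)
}

#' Write a detection table as TSV
#'
#' @param detections A `capwin_detection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections_tsv <- function(detections, path) {
  readr::write_tsv(tidy(detections), path)
  invisible(path)
}
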