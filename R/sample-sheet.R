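#' Read the sample sheet
#'
#' The sample sheet ties each sequencing library to its treatment arm and
#' replicate number and points at its aligned reads. It is a CSV with
#' header columns `sample_id`, `treatment`, `replicate`, `bam_path`.
#'
#' @param path Path to the CSV file.
#' @param check_bams If `TRUE` (default), fail when a listed BAM file does
#'   not exist. Set `FALSE` when working with count tables only.
#' @return A tibble with one row per sample, `replicate` as integer.
#' @export
read_sample_sheet <- function(path, check_bams = TRUE) {
  if (!file.exists(path)) abort(sprintf("sample sheet not found: %s", path))
  sheet <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("failed to parse sample sheet %s: %s",
                                      path, conditionMessage(e)))
  )
  need <- c("sample_id", "treatment", "replicate", "bam_path")
  missing_cols <- setdiff(need, names(sheet))
  if (length(missing_cols) > 0) {
    abort(sprintf("sample sheet %s is missing column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  sheet <- as_tibble(sheet)[, need]
  validate_samples(sheet)
  if (check_bams) {
    absent <- sheet$bam_path[!file.exists(sheet$bam_path)]
    if (length(absent) > 0) {
      abort(sprintf("BAM file(s) not found: %s", paste(absent, collapse = ", ")))
    }
  }
  sheet$replicate <- as.integer(sheet$replicate)
  sheet
}

validate_samples <- function(samples) {
  need <- c("sample_id", "treatment", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    abort("samples must be a data frame with columns sample_id, treatment, replicate")
  }
  if (nrow(samples) == 0) abort("sample sheet has no rows")
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated sample_id: %s", paste(unique(dup), collapse = ", ")))
  }
  key <- paste(samples$treatment, samples$replicate)
  if (anyDuplicated(key)) {
    abort("duplicated (treatment, replicate) pair in sample sheet")
  }
  if (any(!is.finite(samples$replicate) | samples$replicate < 1)) {
    abort("replicate must be a positive integer")
  }
  invisible(samples)
}
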