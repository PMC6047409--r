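#' Count reads per window from a BAM file
#'
#' Counts alignments overlapping each window by at least one base
#' (any-overlap rule, so a read spanning two adjacent windows contributes
#' to both). Alignments that are unmapped, secondary, supplementary or
#' marked duplicate are excluded, as are those below `min_mapq`. In paired
#' mode, properly paired reads are counted once per fragment using the
#' interval spanned by the pair.
#'
#' @param bam Path to an indexed BAM file.
#' @param windows A window set tibble (see [read_windows()]).
#' @param min_mapq Minimum mapping quality; alignments with MAPQ below this
#'   are ignored. Default 10, a common ATAC-seq choice.
#' @param paired Count properly paired reads as single fragments.
#' @return Integer vector of counts, one per window, in window order.
#' @export
count_reads <- function(bam, windows, min_mapq = 10, paired = FALSE) {
  validate_windows(windows)
  assert_flag(paired, "paired")
  assert_number(min_mapq, "min_mapq", lower = 0)
  if (!file.exists(bam)) abort(sprintf("BAM file not found: %s", bam))
  idx <- paste0(bam, ".bai")
  idx2 <- sub("\\.bam$", ".bai", bam)
  if (!file.exists(idx) && !file.exists(idx2)) {
    abort(sprintf("BAM index (.bai) not found for %s; index with samtools index", bam))
  }

  bf <- Rsamtools::BamFile(bam)
  header_chroms <- names(Rsamtools::scanBamHeader(bf)$targets)
  absent <- setdiff(unique(windows$chrom), header_chroms)
  if (length(absent) > 0) {
    warn(sprintf(
      "chromosome(s) %s not in BAM header of %s; their windows get zero counts",
      paste(absent, collapse = ", "), bam
    ))
  }
  present <- !(windows$chrom %in% absent)
  counts <- integer(nrow(windows))
  if (!any(present)) return(counts)

  gr <- GenomicRanges::GRanges(
    seqnames = windows$chrom[present],
    ranges = IRanges::IRanges(start = windows$start[present] + 1L,
                              end = windows$end[present])
  )
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = FALSE,
    isProperPair = if (paired) TRUE else NA
  )
  param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = as.integer(min_mapq))

  if (paired) {
    aln <- GenomicAlignments::readGAlignmentPairs(bf, param = param)
    frag <- GenomicRanges::granges(aln, on.discordant.seqnames = "drop")
  } else {
    aln <- GenomicAlignments::readGAlignments(bf, param = param)
    frag <- GenomicRanges::granges(aln)
  }
  counts[present] <- GenomicRanges::countOverlaps(gr, frag, minoverlap = 1L)
  counts
}

#' Assemble a window-by-sample count experiment from BAM files
#'
#' Runs [count_reads()] for every sample in the sheet and collects the
#' results into a `capwin_experiment`, the container the rest of the
#' package operates on. Deterministic given its inputs.
#'
#' @param samples Sample sheet tibble (see [read_sample_sheet()]).
#' @param windows Window set tibble (see [read_windows()]).
#' @inheritParams count_reads
#' @return A `capwin_experiment` object.
#' @export
build_experiment <- function(samples, windows, min_mapq = 10, paired = FALSE) {
  validate_samples(samples)
  validate_windows(windows)
  counts <- matrix(
    0L, nrow = nrow(windows), ncol = nrow(samples),
    dimnames = list(windows$window_id, samples$sample_id)
  )
  for (s in seq_len(nrow(samples))) {
    counts[, s] <- tryCatch(
      count_reads(samples$bam_path[s], windows, min_mapq = min_mapq, paired = paired),
      error = function(e) abort(sprintf(
        "counting failed for sample '%s': %s", samples$sample_id[s], conditionMessage(e)
      ))
    )
  }
  new_experiment(windows, samples, counts)
}
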