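# shared fixture builders; everything is generated in code at test time

make_windows <- function(n = 4, chrom = "chr1", width = 100L,
                         target_class = "on_target") {
  tibble::tibble(
    chrom = chrom,
    start = (seq_len(n) - 1L) * width,
    end = seq_len(n) * width,
    window_id = sprintf("win_%02d", seq_len(n)),
    target_class = rep(target_class, length.out = n)
  )
}

make_samples <- function(treatments = c("ctrl", "treat"), reps = 2) {
  tibble::tibble(
    sample_id = paste0(rep(treatments, each = reps), "_", seq_len(reps)),
    treatment = rep(treatments, each = reps),
    replicate = rep(seq_len(reps), length(treatments)),
    bam_path = NA_character_
  )
}

# experiment straight from a count matrix; windows/samples derived to fit
make_experiment <- function(counts, treatments = NULL, target_class = "on_target") {
  counts <- as.matrix(counts)
  windows <- make_windows(nrow(counts), target_class = target_class)
  if (is.null(treatments)) {
    half <- ceiling(ncol(counts) / 2)
    treatments <- rep(c("ctrl", "treat"), c(half, ncol(counts) - half))
  }
  samples <- tibble::tibble(
    sample_id = paste0("s", seq_len(ncol(counts))),
    treatment = treatments,
    replicate = stats::ave(seq_along(treatments), treatments, FUN = seq_along),
    bam_path = NA_character_
  )
  new_experiment(windows, samples, counts)
}

# Write a SAM file with simple 10M-cigar single-end reads and convert it to
# an indexed BAM. `reads` is a data frame: qname, chrom, pos (1-based),
# mapq, flag (default 0), cigar.
make_bam <- function(reads, chroms = c(chr1 = 10000L, chr2 = 10000L),
                     dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  reads <- reads[order(match(reads$chrom, names(chroms)), reads$pos), ]
  flag <- if ("flag" %in% names(reads)) reads$flag else rep(0L, nrow(reads))
  cigar <- if ("cigar" %in% names(reads)) reads$cigar else rep("10M", nrow(reads))
  seqlen <- as.integer(sub("M.*", "", cigar))
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
    reads$qname, flag, reads$chrom, reads$pos, reads$mapq, cigar,
    strrep("A", seqlen), strrep("I", seqlen)
  )
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE)
  bam
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
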