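test_that("BED windows are read in native 0-based half-open coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tbait_01",
               "chr1\t500\t700\toff_01",
               "chr2\t0\t50\tctrl_01"), bed)
  win <- read_windows(bed, target_class_rule = c(off_target = "^off",
                                                 control = "^ctrl"))
  expect_tibble(win)
  expect_equal(win$start, c(100L, 500L, 0L))
  expect_equal(win$end, c(200L, 700L, 50L))
  expect_equal(win$target_class, c("on_target", "off_target", "control"))
})

test_that("GFF3 coordinates are converted from 1-based closed on read", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tregion\t101\t200\t.\t+\t.\tID=bait_01",
               "chr1\tsrc\tregion\t1\t50\t.\t+\t.\tID=bait_02"), gff)
  win <- read_windows(gff)
  expect_equal(win$start, c(100L, 0L))
  expect_equal(win$end, c(200L, 50L))
  expect_equal(win$window_id, c("bait_01", "bait_02"))
  expect_equal(win$target_class, c("on_target", "on_target"))
})

test_that("malformed and inverted window records are rejected with context", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tok", "chr1\t200"), bed)
  expect_error(read_windows(bed), "line 2")

  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t200\t100\tbad", bed2)
  expect_error(read_windows(bed2), "start < end")

  bed3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10\tdup", "chr1\t20\t30\tdup"), bed3)
  expect_error(read_windows(bed3), "duplicated window_id")
})

test_that("windows round-trip exactly through BED", {
  set.seed(11)
  win <- make_windows(20)
  win$start <- as.integer(sort(sample.int(1e6, 20)))
  win$end <- win$start + sample.int(500, 20)
  path <- withr::local_tempfile(fileext = ".bed")
  write_windows_bed(win, path)
  back <- read_windows(path)
  expect_equal(back$chrom, win$chrom)
  expect_equal(back$start, win$start)
  expect_equal(back$end, win$end)
  expect_equal(back$window_id, win$window_id)
})

test_that("sample sheets are validated", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,treatment,replicate,bam_path",
               sprintf("%s_%d,%s,%d,na.bam",
                       rep(c("ctrl", "treat"), each = 3),
                       rep(1:3, 2), rep(c("ctrl", "treat"), each = 3),
                       rep(1:3, 2))), csv)
  sheet <- read_sample_sheet(csv, check_bams = FALSE)
  expect_equal(nrow(sheet), 6)
  expect_type(sheet$replicate, "integer")
  expect_error(read_sample_sheet(csv), "not found")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,treatment,replicate,bam_path",
               "ctrl_1,ctrl,1,x.bam", "ctrl_1,ctrl,2,y.bam"), dup)
  expect_error(read_sample_sheet(dup, check_bams = FALSE), "duplicated sample_id")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,treatment", bad)
  expect_error(read_sample_sheet(bad, check_bams = FALSE), "missing column")
})

test_that("experiment container enforces shape and subsets by class", {
  win <- make_windows(10)
  win$target_class <- rep(c("on_target", "off_target"), c(7, 3))
  samples <- make_samples()
  counts <- matrix(seq_len(40), 10, 4)
  exp <- new_experiment(win, samples, counts)

  expect_error(new_experiment(win, samples, counts[1:5, ]), "5 x 4")
  expect_error(new_experiment(win, samples, counts - 100), "non-negative")

  on <- subset_by(exp, "on_target")
  off <- subset_by(exp, "off_target")
  expect_equal(nrow(on$windows), 7)
  expect_equal(nrow(off$windows), 3)
  expect_error(subset_by(exp, "control"), "control")
  # partition: classes are disjoint and cover everything
  expect_setequal(c(on$windows$window_id, off$windows$window_id),
                  exp$windows$window_id)
  # by = "all" is an identity
  expect_equal(subset_by(exp, "all")$counts, exp$counts)

  # layers are subset identically
  exp$layers$normalized <- exp$counts * 0.5
  expect_equal(subset_by(exp, "on_target")$layers$normalized,
               exp$layers$normalized[1:7, ])
})

test_that("tidy() gives one annotated row per window x sample", {
  exp <- make_experiment(matrix(1:12, 3, 4))
  long <- tidy(exp)
  expect_equal(nrow(long), 12)
  expect_named(long, c("window_id", "chrom", "start", "end", "target_class",
                       "sample_id", "treatment", "replicate", "count"))
  expect_equal(sum(long$count), sum(exp$counts))
})

test_that("count TSVs round-trip through write/read", {
  exp <- make_experiment(matrix(rpois(24, 50), 6, 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(exp, path)
  back <- read_counts_tsv(path, windows = exp$windows, samples = exp$samples)
  expect_equal(back$counts, exp$counts)
  expect_equal(back$windows$target_class, exp$windows$target_class)
})
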