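#' Read genomic windows from a BED or GFF3 file
#'
#' Windows are the units of counting in a capture experiment: typically the
#' bait (on-target) intervals plus any off-target or control regions the
#' user wants tracked. Coordinates are held internally in the 0-based
#' half-open convention (as in BED); GFF3 input (1-based, closed) is
#' converted on read (`start - 1`, `end` unchanged).
#'
#' @param path Path to a BED3/BED4 or GFF3 file. Format is guessed from the
#'   file extension unless `format` is given.
#' @param target_class_rule Optional named character vector of regular
#'   expressions used to classify windows from their name (BED column 4 or
#'   the GFF3 `ID`/`Name` attribute). Names must be among `"on_target"`,
#'   `"off_target"`, `"control"`; the first matching pattern wins and
#'   unmatched windows default to `"on_target"`.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return A window set: a tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open), `window_id` and `target_class`.
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tbait_01", "chr1\t500\t700\toff_01"), bed)
#' read_windows(bed, target_class_rule = c(off_target = "^off"))
read_windows <- function(path, target_class_rule = NULL,
                         format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("window file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  win <- if (format == "bed") read_windows_bed(path) else read_windows_gff3(path)

  bad <- which(!(win$start >= 0 & win$start < win$end))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid interval for window '%s': start %d, end %d (need 0 <= start < end)",
      win$window_id[bad[1]], win$start[bad[1]], win$end[bad[1]]
    ))
  }
  dup <- win$window_id[duplicated(win$window_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated window_id: %s", paste(unique(dup), collapse = ", ")))
  }
  win$target_class <- classify_windows(win$window_id, target_class_rule)
  win
}

read_windows_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) abort(sprintf("no window records in %s", path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    f <- fields[[k]]
    if (length(f) < 3) {
      abort(sprintf("malformed BED line %d in %s: fewer than 3 fields", idx[k], path))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("malformed BED line %d in %s: non-numeric coordinates", idx[k], path))
    }
    out[[k]] <- tibble(
      chrom = f[1], start = start, end = end,
      window_id = if (length(f) >= 4 && nzchar(f[4])) f[4] else sprintf("%s:%d-%d", f[1], start, end)
    )
  }
  bind_rows(out)
}

read_windows_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(sprintf("failed to parse GFF3 %s: %s", path, conditionMessage(e)))
  )
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else rep(NA_character_, length(gr))
  wid <- ifelse(!is.na(id) & nzchar(id), id, nm)
  # GRanges is 1-based closed; shift to 0-based half-open
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  wid <- ifelse(
    !is.na(wid) & nzchar(wid), wid,
    sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)), start0, end0)
  )
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0, window_id = wid
  )
}

classify_windows <- function(ids, rule) {
  cls <- rep("on_target", length(ids))
  if (is.null(rule)) return(cls)
  if (is.null(names(rule)) || !all(names(rule) %in% c("on_target", "off_target", "control"))) {
    abort("`target_class_rule` must be a named vector with names among on_target, off_target, control")
  }
  for (k in seq_along(rule)) {
    hit <- grepl(rule[[k]], ids) & cls == "on_target"
    cls[hit] <- names(rule)[k]
  }
  cls
}

#' Write a window set to BED4
#'
#' Internal coordinates are already 0-based half-open, so this is a direct
#' dump; [read_windows()] on the result round-trips exactly.
#'
#' @param windows A window set tibble as returned by [read_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  validate_windows(windows)
  readr::write_tsv(
    windows[, c("chrom", "start", "end", "window_id")],
    path, col_names = FALSE
  )
  invisible(path)
}

validate_windows <- function(windows) {
  need <- c("chrom", "start", "end", "window_id")
  if (!is.data.frame(windows) || !all(need %in% names(windows))) {
    abort("windows must be a data frame with columns chrom, start, end, window_id")
  }
  if (nrow(windows) == 0) abort("window set is empty")
  if (anyDuplicated(windows$window_id)) abort("window_id values must be unique")
  if (any(windows$start < 0 | windows$end <= windows$start)) {
    abort("windows must satisfy 0 <= start < end")
  }
  invisible(windows)
}

#' Mark control windows in a window set
#'
#' Control windows are regions the user asserts should not change between
#' treatments; they anchor [control_window_factors()]. Controls may be given
#' as a character vector of window ids, a window-set tibble, or a path to a
#' file holding either BED4 records or one window id per line
#' (auto-detected). Matching is by `window_id` first, with exact interval
#' match as fallback.
#'
#' @param windows A window set tibble.
#' @param controls Character ids, a tibble of windows, or a file path.
#' @return The window set with `target_class` set to `"control"` for the
#'   matched windows.
#' @export
set_control_windows <- function(windows, controls) {
  validate_windows(windows)
  ctrl <- resolve_controls(controls)
  if (is.character(ctrl)) {
    hit <- windows$window_id %in% ctrl
    missed <- setdiff(ctrl, windows$window_id)
  } else {
    hit <- windows$window_id %in% ctrl$window_id
    missed_ids <- setdiff(ctrl$window_id, windows$window_id)
    if (length(missed_ids) > 0) {
      # fallback: exact interval match for ids not present
      key <- paste(windows$chrom, windows$start, windows$end)
      ckey <- paste(ctrl$chrom, ctrl$start, ctrl$end)[ctrl$window_id %in% missed_ids]
      hit <- hit | key %in% ckey
      missed <- ctrl$window_id[ctrl$window_id %in% missed_ids &
                                 !(paste(ctrl$chrom, ctrl$start, ctrl$end) %in% key)]
    } else {
      missed <- character(0)
    }
  }
  if (!any(hit)) {
    abort(sprintf(
      "no control windows matched the experiment (unmatched: %s)",
      paste(missed, collapse = ", ")
    ))
  }
  if (length(missed) > 0) {
    warn(sprintf("control windows not found: %s", paste(missed, collapse = ", ")))
  }
  windows$target_class[hit] <- "control"
  windows
}

resolve_controls <- function(controls) {
  if (is.character(controls) && length(controls) == 1 && file.exists(controls)) {
    first <- readLines(controls, n = 1L, warn = FALSE)
    if (grepl("\t", first)) return(read_windows_bed(controls))
    ids <- trimws(readLines(controls, warn = FALSE))
    return(ids[nzchar(ids)])
  }
  if (is.character(controls)) return(controls)
  if (is.data.frame(controls)) return(controls)
  abort("`controls` must be a character vector, a window tibble, or a file path")
}
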