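# SEG copy-number segmentation IO.
#
# TCGA SEG files are tab-separated with a header and 1-based *inclusive*
# coordinates; the reader converts to the package-wide 0-based half-open
# convention exactly once, at this boundary. The writer inverts the shift.

#' Read a SEG copy-number segmentation file
#'
#' Reads a tab-separated segmentation table (TCGA convention: header line,
#' 1-based inclusive coordinates) into a segment tibble. Coordinates are
#' converted to the internal 0-based half-open convention
#' (`start - 1`, `end` unchanged) and chromosome names are normalised with
#' [normalize_chrom()].
#'
#' @param path Path to the SEG file.
#' @param col_names Character vector of length 6 mapping the file's columns,
#'   in order, onto `c("sample_id", "chrom", "start", "end", "n_markers",
#'   "seg_mean")`. Use it when the dialect orders or names columns
#'   differently. `NULL` (default) assumes the standard order.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `n_markers`, `seg_mean` — one row per segment.
#' @seealso [write_seg()], [filter_segments()]
#' @examples
#' seg <- tempfile(fileext = ".seg")
#' writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
#'              "S1\tchr4\t91048686\t92523064\t500\t-0.45"), seg)
#' read_seg(seg)
#' @export
read_seg <- function(path, col_names = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) abort(sprintf("SEG file '%s' is empty.", path))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  std <- c("sample_id", "chrom", "start", "end", "n_markers", "seg_mean")
  ord <- seq_len(6)
  if (!is.null(col_names)) {
    if (length(col_names) != 6 || !setequal(col_names, std)) {
      abort("`col_names` must be a permutation of sample_id, chrom, start, end, n_markers, seg_mean.")
    }
    ord <- match(std, col_names)
  }
  if (length(body) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_markers = integer(), seg_mean = numeric()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  parse_row <- function(f, line_no) {
    if (length(f) < 6) {
      abort(sprintf("SEG line %d: expected 6 tab-separated fields, found %d.",
                    line_no, length(f)))
    }
    f <- f[ord]
    start1 <- suppressWarnings(as.numeric(f[3]))
    end1 <- suppressWarnings(as.numeric(f[4]))
    nm <- suppressWarnings(as.integer(f[5]))
    sm <- suppressWarnings(as.numeric(f[6]))
    if (is.na(start1) || is.na(end1)) {
      abort(sprintf("SEG line %d: non-numeric start/end.", line_no))
    }
    if (is.na(sm)) abort(sprintf("SEG line %d: non-numeric seg_mean.", line_no))
    if (end1 < start1) {
      abort(sprintf("SEG line %d: end (%s) before start (%s).", line_no, f[4], f[3]))
    }
    if (is.na(nm) || nm < 0) {
      abort(sprintf("SEG line %d: n_markers must be a non-negative integer.", line_no))
    }
    list(sample_id = f[1], chrom = f[2], start = start1 - 1, end = end1,
         n_markers = nm, seg_mean = sm)
  }
  rows <- purrr::imap(fields, function(f, i) parse_row(f, i + 1L))
  out <- dplyr::bind_rows(rows)
  out$chrom <- normalize_chrom(out$chrom)
  validate_segments(out, "read_seg() output")
  out
}

#' Write segments to a SEG file
#'
#' Inverse of [read_seg()]: internal 0-based half-open coordinates are written
#' back as 1-based inclusive.
#'
#' @param segments Segment tibble (see [read_seg()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  validate_segments(segments)
  df <- data.frame(Sample = segments$sample_id,
                   Chromosome = segments$chrom,
                   Start = format(segments$start + 1, scientific = FALSE, trim = TRUE),
                   End = format(segments$end, scientific = FALSE, trim = TRUE),
                   Num_Probes = segments$n_markers,
                   Segment_Mean = segments$seg_mean)
  readr::write_tsv(df, path)
  invisible(path)
}
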