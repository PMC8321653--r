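# bedGraph coverage IO and the coverage_track container: a dense per-base
# signal over one contiguous chromosome window, the text stand-in for a
# bigwig track.

#' Construct a coverage track
#'
#' A dense, per-base, non-negative signal over one contiguous 0-based
#' half-open window of a chromosome.
#'
#' @param sample_id Track identifier.
#' @param chrom Chromosome name (normalised with [normalize_chrom()]).
#' @param start,end Window, 0-based half-open.
#' @param signal Numeric vector of length `end - start`, non-negative.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(sample_id, chrom, start, end, signal) {
  if (length(signal) != end - start) {
    abort(sprintf("Signal length (%d) must equal end - start (%d).",
                  length(signal), end - start))
  }
  if (any(!is.finite(signal)) || any(signal < 0)) {
    abort("Coverage signal must be finite and non-negative.")
  }
  structure(list(sample_id = sample_id, chrom = normalize_chrom(chrom),
                 start = start, end = end, signal = as.numeric(signal)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s %s:[%d, %d)  mean signal %.3f\n",
              x$sample_id, x$chrom, x$start, x$end, mean(x$signal)))
  invisible(x)
}

#' Read a bedGraph file into a dense coverage track
#'
#' The bedGraph must be coordinate-sorted with non-overlapping records
#' (0-based half-open, the bedGraph convention). Bases of `region` not
#' covered by any record are filled with 0.
#'
#' @param path Path to the bedGraph file.
#' @param region One-row region tibble (or list) with `chrom`, `start`,
#'   `end` giving the window to extract.
#' @param sample_id Track identifier; defaults to the file name.
#' @return A [coverage_track()] over `region`.
#' @seealso [write_bedgraph()]
#' @export
read_bedgraph <- function(path, region, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  rchrom <- normalize_chrom(region$chrom[[1]])
  rstart <- region$start[[1]]
  rend <- region$end[[1]]
  signal <- numeric(rend - rstart)
  if (length(lines)) {
    fields <- strsplit(lines, "[ \t]+")
    if (any(lengths(fields) < 4)) abort("bedGraph: fewer than 4 columns.")
    chrom <- normalize_chrom(purrr::map_chr(fields, 1))
    start <- as.numeric(purrr::map_chr(fields, 2))
    end <- as.numeric(purrr::map_chr(fields, 3))
    value <- as.numeric(purrr::map_chr(fields, 4))
    if (any(is.na(start)) || any(is.na(end)) || any(is.na(value))) {
      abort("bedGraph: non-numeric fields.")
    }
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      if (any(diff(start[i]) < 0)) {
        abort(sprintf("bedGraph '%s' is not coordinate-sorted on %s.", path, ch))
      }
      if (any(start[i][-1] < end[i][-length(i)])) {
        abort(sprintf("bedGraph '%s' has overlapping records on %s.", path, ch))
      }
    }
    sel <- which(chrom == rchrom & end > rstart & start < rend)
    if (length(sel)) {
      a <- pmax(start[sel], rstart) - rstart + 1
      b <- pmin(end[sel], rend) - rstart
      len <- b - a + 1
      signal[sequence(nvec = len, from = a)] <- rep(value[sel], times = len)
    }
  }
  coverage_track(sample_id, rchrom, rstart, rend, signal)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal signal are collapsed into single records; zero runs are
#' omitted (they are implicit on re-read).
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$signal)
  ends <- track$start + cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  lines <- sprintf("%s\t%s\t%s\t%s", track$chrom,
                   format(starts[keep], scientific = FALSE, trim = TRUE),
                   format(ends[keep], scientific = FALSE, trim = TRUE),
                   format(r$values[keep], scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}
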