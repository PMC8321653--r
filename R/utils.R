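# Internal helpers: chromosome-name normalisation and interval arithmetic.
# Every coordinate inside the package is 0-based, half-open [start, end).

#' Normalise chromosome names to the "chrN" form
#'
#' Annotation sources disagree on whether chromosomes carry a "chr" prefix;
#' all readers funnel names through this function so that `"4"`, `"chr4"` and
#' `"Chr4"` meet as `"chr4"`. `"MT"` is mapped to `"chrM"`.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalised names.
#' @examples
#' normalize_chrom(c("4", "chrX", "MT"))
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x[x == "MT"] <- "M"
  paste0("chr", x)
}

# Total length of the union of a set of half-open intervals, after clipping
# to [rstart, rend). Vectorised sorted merge: an interval opens new ground
# only beyond the running maximum of previous ends.
interval_union_length <- function(starts, ends, rstart, rend) {
  s <- pmax(starts, rstart)
  e <- pmin(ends, rend)
  keep <- e > s
  if (!any(keep)) return(0L)
  s <- s[keep]; e <- e[keep]
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  hi <- cummax(e)
  prev_hi <- c(rstart, hi[-length(hi)])
  sum(pmax(0, e - pmax(s, prev_hi)))
}

# Pairwise overlap in bp of each interval with a single region (no union).
interval_overlap_bp <- function(starts, ends, rstart, rend) {
  pmax(0, pmin(ends, rend) - pmax(starts, rstart))
}

stop_if_not_df <- function(x, arg) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame, not %s.", arg, class(x)[1]))
  }
}

require_columns <- function(x, cols, arg) {
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  arg, paste(miss, collapse = ", ")))
  }
}

# Validate a region tibble (0-based half-open) and its invariants.
validate_regions <- function(regions, arg = "regions") {
  stop_if_not_df(regions, arg)
  require_columns(regions, c("chrom", "start", "end", "name"), arg)
  if (any(regions$start < 0)) abort(sprintf("`%s`: start must be >= 0.", arg))
  if (any(regions$end <= regions$start)) {
    abort(sprintf("`%s`: end must be > start for every region.", arg))
  }
  if (anyDuplicated(regions$name)) {
    dup <- unique(regions$name[duplicated(regions$name)])
    abort(sprintf("`%s`: duplicate region name(s): %s.",
                  arg, paste(dup, collapse = ", ")))
  }
  invisible(regions)
}

validate_segments <- function(segments, arg = "segments") {
  stop_if_not_df(segments, arg)
  require_columns(segments, c("sample_id", "chrom", "start", "end", "seg_mean"), arg)
  if (any(!is.finite(segments$seg_mean))) {
    abort(sprintf("`%s`: seg_mean must be finite.", arg))
  }
  if (any(segments$end <= segments$start)) {
    abort(sprintf("`%s`: end must be > start for every segment.", arg))
  }
  invisible(segments)
}

# Deterministic child seeds below 2^31, derived from a user seed.
derive_seed <- function(seed, i) {
  s <- as.numeric(seed) %% 1000003
  as.integer((s * 2011 + 17 * as.numeric(i)) %% 2147483647)
}
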