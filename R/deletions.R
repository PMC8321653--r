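# Deletion calling over named regions: filter segments by log2-ratio, then
# intersect qualifying segments with fragile sites / gene portions /
# pseudogene elements, per patient.

#' Filter copy-number segments by segmentation value
#'
#' Keeps exactly the segments whose `seg_mean` is strictly lower than
#' `threshold` (default −0.1, the focal-deletion filter; the boundary value
#' itself is excluded). Input order is preserved.
#'
#' @param segments Segment tibble (see [read_seg()]).
#' @param threshold Log2 copy-ratio cut-off; segments with
#'   `seg_mean < threshold` survive.
#' @return The filtered segment tibble.
#' @examples
#' segs <- tibble::tibble(sample_id = "S1", chrom = "chr4",
#'                        start = 0, end = c(10, 20, 30, 40),
#'                        n_markers = 5L,
#'                        seg_mean = c(-0.05, -0.1, -0.11, -0.45))
#' filter_segments(segs)$seg_mean
#' @export
filter_segments <- function(segments, threshold = -0.1) {
  validate_segments(segments)
  dplyr::filter(segments, .data$seg_mean < .env$threshold)
}

#' Call per-patient deletions over named regions
#'
#' Intersects already-filtered segments with each region and emits one call
#' per (sample, region) — including samples with no qualifying segment, which
#' are called non-deleted. A region counts as deleted for a sample when at
#' least one qualifying segment overlaps it by >= 1 bp. `overlap_bp` is the
#' number of region bases covered by the union of that sample's qualifying
#' segments; `weighted_seg_value` is the per-segment overlap-weighted mean of
#' `seg_mean` (`NA` when nothing overlaps), the patient-wise segmentation
#' value over the region.
#'
#' @param segments Filtered segment tibble (see [filter_segments()]).
#' @param regions Region tibble (see [read_bed()]).
#' @param samples Character vector of all sample ids to report on; every
#'   sample in `segments` must be listed here.
#' @return Tibble with columns `sample_id`, `region_name`, `deleted`,
#'   `overlap_bp`, `weighted_seg_value`.
#' @examples
#' segs <- tibble::tibble(sample_id = "S1", chrom = "chr1",
#'                        start = 150, end = 250, n_markers = 10L,
#'                        seg_mean = -0.4)
#' reg <- tibble::tibble(chrom = "chr1", start = 100, end = 200,
#'                       name = "R1", strand = ".", kind = "fragile_site")
#' call_deletions(segs, reg, samples = c("S1", "S2"))
#' @export
call_deletions <- function(segments, regions, samples) {
  validate_segments(segments)
  validate_regions(regions)
  extra <- setdiff(unique(segments$sample_id), samples)
  if (length(extra)) {
    abort(sprintf("Segment sample(s) absent from `samples`: %s.",
                  paste(extra, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(sample_id = samples,
                             region_name = regions$name)
  per_region <- purrr::pmap(regions, function(chrom, start, end, name, ...) {
    hit <- segments[segments$chrom == chrom &
                      segments$end > start & segments$start < end, ,
                    drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    hit |>
      dplyr::mutate(ov = interval_overlap_bp(.data$start, .data$end,
                                             .env$start, .env$end)) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(
        region_name = .env$name,
        overlap_bp = interval_union_length(.data$start, .data$end,
                                           .env$start, .env$end),
        weighted_seg_value = sum(.data$ov * .data$seg_mean) / sum(.data$ov),
        .groups = "drop")
  })
  hits <- dplyr::bind_rows(per_region)
  if (nrow(hits) == 0) {
    hits <- tibble::tibble(sample_id = character(), region_name = character(),
                           overlap_bp = numeric(),
                           weighted_seg_value = numeric())
  }
  out <- dplyr::left_join(grid, hits, by = c("sample_id", "region_name"))
  out |>
    dplyr::mutate(
      overlap_bp = dplyr::coalesce(.data$overlap_bp, 0),
      deleted = .data$overlap_bp > 0) |>
    dplyr::select("sample_id", "region_name", "deleted", "overlap_bp",
                  "weighted_seg_value")
}

#' Classify per-sample gene deletion pattern from sub-region calls
#'
#' Given deletion calls over the 5', central and 3' portions of one gene
#' (three disjoint regions partitioning the gene body), labels each sample.
#' Precedence for mixed deletions is 3' > central > other: any overlap of
#' the 3' portion yields `three_prime_deleted`; otherwise central overlap
#' yields `central_deleted`; a 5'-only deletion is `other`; no overlap
#' anywhere is `wild_type`.
#'
#' @param calls Deletion calls (see [call_deletions()]) covering the three
#'   sub-regions for every sample.
#' @param regions Region tibble holding the three sub-regions (used to check
#'   disjointness).
#' @param five_prime,central,three_prime Region names of the gene portions.
#' @return Tibble with columns `sample_id` and `label` (factor with levels
#'   `wild_type`, `central_deleted`, `three_prime_deleted`, `other`).
#' @export
classify_gene_deletion <- function(calls, regions,
                                   five_prime = "five_prime",
                                   central = "central",
                                   three_prime = "three_prime") {
  sub <- regions[regions$name %in% c(five_prime, central, three_prime), ,
                 drop = FALSE]
  if (nrow(sub) != 3) abort("The three sub-regions must all be present in `regions`.")
  sub <- sub[order(sub$start), ]
  if (length(unique(sub$chrom)) != 1 || any(sub$start[-1] < sub$end[-3])) {
    abort("Gene sub-regions must be disjoint intervals on one chromosome.")
  }
  wide <- calls[calls$region_name %in% sub$name, c("sample_id", "region_name", "deleted")] |>
    tidyr::pivot_wider(names_from = "region_name", values_from = "deleted")
  require_columns(wide, c(five_prime, central, three_prime), "calls")
  lab <- dplyr::case_when(
    wide[[three_prime]] ~ "three_prime_deleted",
    wide[[central]] ~ "central_deleted",
    wide[[five_prime]] ~ "other",
    TRUE ~ "wild_type")
  tibble::tibble(sample_id = wide$sample_id,
                 label = factor(lab, levels = c("wild_type", "central_deleted",
                                                "three_prime_deleted", "other")))
}

#' Fraction of deletion events overlapping an element
#'
#' Among deletion events already restricted to a gene of interest, counts
#' those that also overlap a smaller element (e.g., an intronic pseudogene)
#' by at least 1 bp under the half-open convention, and reports the fraction.
#'
#' @param events Segment tibble of deletion events (one row per event).
#' @param element One-row region tibble (or list) with `chrom`, `start`,
#'   `end`.
#' @return Tibble with one row: `n_events`, `n_overlapping`, `fraction`
#'   (`NA` with a warning when `n_events` is 0).
#' @examples
#' ev <- tibble::tibble(sample_id = c("a", "b", "c", "d"), chrom = "chr4",
#'                      start = c(0, 50, 120, 300), end = c(40, 110, 160, 400),
#'                      n_markers = 1L, seg_mean = -0.5)
#' overlap_fraction_events(ev, list(chrom = "chr4", start = 100, end = 200))
#' @export
overlap_fraction_events <- function(events, element) {
  validate_segments(events, "events")
  chrom <- normalize_chrom(element$chrom[[1]])
  ov <- events$chrom == chrom &
    interval_overlap_bp(events$start, events$end,
                        element$start[[1]], element$end[[1]]) > 0
  n <- nrow(events)
  if (n == 0) {
    warn("No events supplied; overlap fraction is undefined.")
    return(tibble::tibble(n_events = 0L, n_overlapping = 0L,
                          fraction = NA_real_))
  }
  tibble::tibble(n_events = n, n_overlapping = sum(ov), fraction = sum(ov) / n)
}
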