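# Nascent-transcription (TT-seq style) exon expression: per-exon,
# length-normalised coverage signal per sample, summed over samples,
# log(1 + sum)-transformed and rescaled to [0, 1]; plus a summary statistic
# for the signal drop downstream of an intragenic element.

# Exons ordered along the transcription direction: coordinate order for
# plus-strand genes, reversed for minus-strand.
exon_transcription_order <- function(exons) {
  o <- order(exons$start)
  strand <- if ("strand" %in% names(exons)) exons$strand[o][1] else "+"
  if (identical(strand, "-")) o <- rev(o)
  o
}

#' Length-normalised exon signal per coverage track
#'
#' For each exon and track, sums the per-base signal over the exon and
#' divides by exon length: `E = sum(signal) / length`.
#'
#' @param tracks List of [coverage_track()] objects; every track must cover
#'   every exon interval.
#' @param exons Region tibble of the gene's exons (non-overlapping; exon
#'   ordinals follow transcription direction, so minus-strand exon lists are
#'   reversed).
#' @return Tibble with one row per (exon, track): `exon_index` (1-based,
#'   transcription order), `exon_name`, `sample_id`, `E`.
#' @export
exon_signal <- function(tracks, exons) {
  validate_regions(exons, "exons")
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  o <- exon_transcription_order(exons)
  exons <- exons[o, , drop = FALSE]
  rows <- purrr::imap(tracks, function(tr, ti) {
    if (!inherits(tr, "coverage_track")) abort("`tracks` must contain coverage_track objects.")
    outside <- exons$chrom != tr$chrom | exons$start < tr$start |
      exons$end > tr$end
    if (any(outside)) {
      abort(sprintf("Exon '%s' lies outside the extent of track '%s'.",
                    exons$name[which(outside)[1]], tr$sample_id))
    }
    E <- purrr::map2_dbl(exons$start, exons$end, function(s, e) {
      idx <- (s - tr$start + 1):(e - tr$start)
      sum(tr$signal[idx]) / (e - s)
    })
    tibble::tibble(exon_index = seq_len(nrow(exons)),
                   exon_name = exons$name,
                   sample_id = tr$sample_id, E = E)
  })
  dplyr::bind_rows(rows)
}

#' Exon expression from length-normalised signal
#'
#' Sums the per-sample signal `E` within each exon and applies the natural
#' log transform `log(1 + sum E)`.
#'
#' @param raw_E Tibble from [exon_signal()] (columns `exon_index`, `E`).
#' @return Tibble with one row per exon: `exon_index`, `total_E`,
#'   `expression`.
#' @export
exon_expression <- function(raw_E) {
  stop_if_not_df(raw_E, "raw_E")
  require_columns(raw_E, c("exon_index", "E"), "raw_E")
  if (any(raw_E$E < 0)) abort("Length-normalised signal must be non-negative.")
  raw_E |>
    dplyr::group_by(.data$exon_index) |>
    dplyr::summarise(total_E = sum(.data$E),
                     expression = log1p(sum(.data$E)), .groups = "drop") |>
    dplyr::arrange(.data$exon_index)
}

#' Rescale a vector to the unit interval
#'
#' `(x - min) / (max - min)`; a constant vector maps to all zeros with a
#' warning. Order of values is preserved.
#'
#' @param x Numeric vector of length >= 2.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' rescale_unit(c(0, 1, 2))
#' @export
rescale_unit <- function(x) {
  if (length(x) < 2) abort("`x` must have length >= 2.")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warn("Constant vector: rescaled values set to 0.")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Full TT-seq style exon expression profile
#'
#' Chains [exon_signal()], [exon_expression()] and [rescale_unit()]: per
#' exon, length-normalised signal summed over all tracks, natural-log
#' transformed and rescaled to `[0, 1]`.
#'
#' @inheritParams exon_signal
#' @return Tibble of class `fx_exon_profile` with one row per exon:
#'   `exon_index`, `exon_name`, `total_E`, `expression`, `rescaled`.
#' @examples
#' exons <- tibble::tibble(chrom = "chr4", start = c(0, 200),
#'                         end = c(100, 300), name = c("e1", "e2"),
#'                         strand = "+", kind = "exon")
#' tr <- coverage_track("t1", "chr4", 0, 300, rep(2, 300))
#' ttseq_exon_profile(list(tr), exons)
#' @export
ttseq_exon_profile <- function(tracks, exons) {
  raw <- exon_signal(tracks, exons)
  expr <- exon_expression(raw)
  expr$exon_name <- raw$exon_name[match(expr$exon_index, raw$exon_index)]
  expr$rescaled <- rescale_unit(expr$expression)
  out <- expr[, c("exon_index", "exon_name", "total_E", "expression", "rescaled")]
  class(out) <- c("fx_exon_profile", class(out))
  out
}

#' Post-element drop in exon expression
#'
#' Signed summary of the change in rescaled exon expression across an
#' intragenic element sitting between exon `k` and exon `k + 1`
#' (transcription order): mean rescaled expression of exons after the
#' element minus mean of exons up to and including exon `k`. Negative
#' values indicate reduced transcription downstream of the element.
#'
#' @param profile Tibble from [ttseq_exon_profile()] (columns `exon_index`,
#'   `rescaled`).
#' @param k Index of the last exon upstream of the element
#'   (`1 <= k < number of exons`).
#' @return The drop statistic (a single number).
#' @export
post_element_drop <- function(profile, k) {
  stop_if_not_df(profile, "profile")
  require_columns(profile, c("exon_index", "rescaled"), "profile")
  n <- max(profile$exon_index)
  if (k < 1 || k >= n) {
    abort(sprintf("`k` must be in [1, %d); got %s.", n, format(k)))
  }
  mean(profile$rescaled[profile$exon_index > k]) -
    mean(profile$rescaled[profile$exon_index <= k])
}
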