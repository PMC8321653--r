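# Gene-wise z-scores of tumour expression against the normal-tissue
# reference of the same tumour type.

#' Z-score tumour expression against normal tissue
#'
#' For one tumour type, estimates each gene's mean and standard deviation
#' (denominator n − 1) from the normal samples of that type and converts
#' every tumour sample to `z = (x − mu) / sd`. Expression is transformed as
#' `log(1 + FPKM)` first by default; genes whose normal-tissue SD is zero
#' are dropped and reported.
#'
#' @param panel An [expression_panel()].
#' @param tumour_type Tumour type to analyse (must have >= 2 normal
#'   samples).
#' @param log_transform Apply `log1p` before z-scoring (default `TRUE`).
#' @return Object of class `zscore_panel`: `z` (genes x tumour-sample
#'   matrix), `reference` (tibble `gene_id`, `mu`, `sd`), `dropped`
#'   (character vector of zero-variance genes), `samples` (tumour-sample
#'   metadata), `tumour_type`, `log_transform`.
#' @examples
#' m <- matrix(c(1, 3, 4, 2), 1, 4,
#'             dimnames = list("g1", paste0("s", 1:4)))
#' p <- expression_panel(m, tibble::tibble(
#'   sample_id = paste0("s", 1:4), tumour_type = "TT",
#'   is_tumour = c(FALSE, FALSE, TRUE, TRUE), purity = NA_real_))
#' zscore_vs_normal(p, "TT", log_transform = FALSE)$z
#' @export
zscore_vs_normal <- function(panel, tumour_type, log_transform = TRUE) {
  if (!inherits(panel, "expression_panel")) {
    abort("`panel` must be an expression_panel.")
  }
  meta <- panel$samples
  norm_ids <- meta$sample_id[!meta$is_tumour & meta$tumour_type == tumour_type]
  tum_ids <- meta$sample_id[meta$is_tumour & meta$tumour_type == tumour_type]
  if (length(norm_ids) < 2) {
    abort(sprintf(
      "Need >= 2 normal samples of tumour type '%s' to estimate mean and SD (found %d).",
      tumour_type, length(norm_ids)))
  }
  x <- panel$values
  if (log_transform) x <- log1p(x)
  xn <- x[, norm_ids, drop = FALSE]
  mu <- rowMeans(xn)
  sigma <- apply(xn, 1, sd)
  keep <- sigma > 0
  dropped <- rownames(x)[!keep]
  z <- sweep(sweep(x[keep, tum_ids, drop = FALSE], 1, mu[keep], "-"),
             1, sigma[keep], "/")
  structure(list(z = z,
                 reference = tibble::tibble(gene_id = rownames(x)[keep],
                                            mu = unname(mu[keep]),
                                            sd = unname(sigma[keep])),
                 dropped = dropped,
                 samples = meta[match(tum_ids, meta$sample_id), , drop = FALSE],
                 tumour_type = tumour_type,
                 log_transform = log_transform),
            class = "zscore_panel")
}

#' @export
print.zscore_panel <- function(x, ...) {
  cat(sprintf("<zscore_panel> %s: %d genes x %d tumour samples (%d gene(s) dropped for zero normal SD)\n",
              x$tumour_type, nrow(x$z), ncol(x$z), length(x$dropped)))
  invisible(x)
}

#' Tidy a z-score panel into a long tibble
#'
#' @param x A `zscore_panel` from [zscore_vs_normal()].
#' @param ... Unused.
#' @return Tibble with `gene_id`, `sample_id`, `z` and the sample metadata.
#' @export
tidy.zscore_panel <- function(x, ...) {
  long <- tibble::tibble(
    gene_id = rep(rownames(x$z), times = ncol(x$z)),
    sample_id = rep(colnames(x$z), each = nrow(x$z)),
    z = as.vector(x$z))
  dplyr::left_join(long, x$samples, by = "sample_id")
}
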