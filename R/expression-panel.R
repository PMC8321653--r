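# The expression panel: an FPKM matrix (genes x samples) plus per-sample and
# per-gene metadata. Kept as a light S3 class around a numeric matrix because
# z-scoring and signature scoring are matrix operations; tidy() gives the
# long-tibble view.

#' Construct an expression panel
#'
#' Bundles a non-negative FPKM matrix (genes in rows, samples in columns)
#' with per-sample metadata (tumour type, tumour/normal flag, tumour purity)
#' and per-gene flags (protein-coding status).
#'
#' @param values Numeric matrix of FPKM, genes x samples, non-negative.
#' @param samples Tibble with columns `sample_id`, `tumour_type`,
#'   `is_tumour` (logical) and `purity` (in `[0, 1]`, `NA` allowed; ignored
#'   and set `NA` for normals).
#' @param genes Tibble with columns `gene_id` and `protein_coding`
#'   (logical). Defaults to all protein-coding.
#' @return An object of class `expression_panel`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_panel(m, tibble::tibble(
#'   sample_id = c("s1", "s2"), tumour_type = "TT",
#'   is_tumour = c(TRUE, FALSE), purity = c(0.7, NA)))
#' @export
expression_panel <- function(values, samples, genes = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  stop_if_not_df(samples, "samples")
  require_columns(samples, c("sample_id", "tumour_type", "is_tumour"), "samples")
  if (!"purity" %in% names(samples)) samples$purity <- NA_real_
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene_ids as rownames and sample_ids as colnames.")
  }
  if (is.null(genes)) {
    genes <- tibble::tibble(gene_id = rownames(values), protein_coding = TRUE)
  }
  require_columns(genes, c("gene_id", "protein_coding"), "genes")
  if (!identical(sort(colnames(values)), sort(samples$sample_id))) {
    abort("Sample ids in `values` columns and `samples` metadata do not match.")
  }
  if (!identical(sort(rownames(values)), sort(as.character(genes$gene_id)))) {
    abort("Gene ids in `values` rows and `genes` metadata do not match.")
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  genes <- genes[match(rownames(values), genes$gene_id), , drop = FALSE]
  if (any(values < 0, na.rm = TRUE)) abort("FPKM values must be non-negative.")
  bad_purity <- !is.na(samples$purity) &
    (samples$purity < 0 | samples$purity > 1)
  if (any(bad_purity)) {
    abort(sprintf("Purity outside [0, 1] for sample(s): %s.",
                  paste(samples$sample_id[bad_purity], collapse = ", ")))
  }
  structure(list(values = values,
                 samples = tibble::as_tibble(samples),
                 genes = tibble::as_tibble(genes)),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("<expression_panel> %d genes x %d samples (%d tumour, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$samples$is_tumour), sum(!x$samples$is_tumour)))
  cat(sprintf("  tumour types: %s\n",
              paste(unique(x$samples$tumour_type), collapse = ", ")))
  cat(sprintf("  purity known for %d/%d tumour samples\n",
              sum(!is.na(x$samples$purity) & x$samples$is_tumour),
              sum(x$samples$is_tumour)))
  invisible(x)
}

#' Tidy an expression panel into a long tibble
#'
#' @param x An [expression_panel()].
#' @param ... Unused.
#' @return Tibble with one row per (gene, sample): `gene_id`, `sample_id`,
#'   `fpkm`, joined with the sample metadata.
#' @export
tidy.expression_panel <- function(x, ...) {
  long <- tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    fpkm = as.vector(x$values))
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Read an FPKM expression matrix and its sample metadata
#'
#' The matrix file is TSV with gene ids in the first column and one column
#' per sample; the metadata file is TSV with columns `sample_id`,
#' `tumour_type`, `is_tumour`, `purity` (empty purity cells become `NA`).
#' An optional gene table supplies `protein_coding` flags.
#'
#' @param path_matrix Path to the genes x samples FPKM TSV.
#' @param path_metadata Path to the sample metadata TSV.
#' @param path_genes Optional path to a TSV with columns `gene_id`,
#'   `protein_coding`; when `NULL` all genes are flagged protein-coding.
#' @return An [expression_panel()].
#' @seealso [write_expression()]
#' @export
read_expression <- function(path_matrix, path_metadata, path_genes = NULL) {
  mat_df <- readr::read_tsv(path_matrix, show_col_types = FALSE,
                            progress = FALSE)
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(values) <- as.character(mat_df[[1]])
  meta <- readr::read_tsv(path_metadata, show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(
                            sample_id = readr::col_character(),
                            tumour_type = readr::col_character(),
                            is_tumour = readr::col_logical(),
                            purity = readr::col_double()))
  missing_meta <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_meta)) {
    abort(sprintf("Sample(s) in matrix but absent from metadata: %s.",
                  paste(missing_meta, collapse = ", ")))
  }
  meta <- meta[meta$sample_id %in% colnames(values), , drop = FALSE]
  genes <- NULL
  if (!is.null(path_genes)) {
    genes <- readr::read_tsv(path_genes, show_col_types = FALSE,
                             progress = FALSE)
    genes$protein_coding <- as.logical(genes$protein_coding)
  }
  expression_panel(values, meta, genes)
}

#' Write an expression panel to TSV files
#'
#' @param panel An [expression_panel()].
#' @param path_matrix,path_metadata,path_genes Output paths (genes file
#'   skipped when `path_genes` is `NULL`).
#' @return `path_matrix`, invisibly.
#' @export
write_expression <- function(panel, path_matrix, path_metadata,
                             path_genes = NULL) {
  df <- data.frame(gene_id = rownames(panel$values), panel$values,
                   check.names = FALSE)
  readr::write_tsv(df, path_matrix)
  readr::write_tsv(panel$samples, path_metadata)
  if (!is.null(path_genes)) readr::write_tsv(panel$genes, path_genes)
  invisible(path_matrix)
}
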