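# Shared in-code fixtures: tiny files written to tempdir and small
# constructors used across the test files.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A minimal 3-gene x 4-sample panel (one normal) written to TSV files.
tiny_expression_files <- function(purity = c(0.8, 0.6, 0.9, NA)) {
  mat <- write_lines_tmp(c(
    "gene_id\ts1\ts2\ts3\ts4",
    "g1\t1\t2\t3\t4",
    "g2\t5\t6\t7\t8",
    "g3\t0\t0.5\t1\t1.5"), ".tsv")
  meta <- write_lines_tmp(c(
    "sample_id\ttumour_type\tis_tumour\tpurity",
    sprintf("s1\tTT\tTRUE\t%s", ifelse(is.na(purity[1]), "", purity[1])),
    sprintf("s2\tTT\tTRUE\t%s", ifelse(is.na(purity[2]), "", purity[2])),
    sprintf("s3\tTT\tTRUE\t%s", ifelse(is.na(purity[3]), "", purity[3])),
    sprintf("s4\tTT\tFALSE\t%s", ifelse(is.na(purity[4]), "", purity[4]))),
    ".tsv")
  list(matrix = mat, metadata = meta)
}

# Segment tibble builder with sensible defaults.
seg_tbl <- function(sample_id = "S1", chrom = "chr1", start = 0, end = 100,
                    n_markers = 10L, seg_mean = -0.5) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, start = start,
                 end = end, n_markers = n_markers, seg_mean = seg_mean)
}

region_tbl <- function(chrom = "chr1", start = 0, end = 100, name = "R1",
                       strand = ".", kind = "fragile_site") {
  tibble::tibble(chrom = chrom, start = start, end = end, name = name,
                 strand = strand, kind = kind)
}

# Panel with explicit normal values per gene; tumour values supplied as a
# genes x tumour matrix on the FPKM scale.
panel_from_values <- function(tumour, normal, tumour_type = "TT",
                              purity = NULL) {
  stopifnot(nrow(tumour) == nrow(normal))
  n_t <- ncol(tumour)
  n_n <- ncol(normal)
  values <- cbind(tumour, normal)
  rownames(values) <- paste0("g", seq_len(nrow(values)))
  colnames(values) <- c(sprintf("t%02d", seq_len(n_t)),
                        sprintf("n%02d", seq_len(n_n)))
  if (is.null(purity)) purity <- rep(1, n_t)
  expression_panel(values, tibble::tibble(
    sample_id = colnames(values),
    tumour_type = tumour_type,
    is_tumour = c(rep(TRUE, n_t), rep(FALSE, n_n)),
    purity = c(purity, rep(NA_real_, n_n))))
}

# Independent per-base overlap oracle: counts region bases covered by >= 1
# segment by explicit membership over every base.
brute_force_overlap <- function(starts, ends, rstart, rend) {
  if (rend <= rstart) return(0L)
  bases <- rstart:(rend - 1)
  covered <- rep(FALSE, length(bases))
  for (i in seq_along(starts)) {
    covered <- covered | (bases >= starts[i] & bases < ends[i])
  }
  sum(covered)
}

# Independent exact Mann-Whitney oracle: U from pairwise comparisons, p by
# enumerating every assignment of the pooled values to group 1.
brute_force_mw <- function(x, y) {
  U_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U_obs <- U_of(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  U_all <- apply(combos, 2, function(idx) {
    U_of(pooled[idx], pooled[-idx])
  })
  eps <- 1e-9
  p <- min(1, 2 * min(mean(U_all <= U_obs + eps), mean(U_all >= U_obs - eps)))
  list(U = U_obs, p = p)
}
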