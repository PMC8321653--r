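# The deletion-expression association: per gene, regress the z-scored
# expression of tumour samples on deletion status with tumour purity as an
# additional covariate, using the biweight robust linear model; then
# Bonferroni-correct over the fitted family and restrict to protein-coding
# genes below the significance cut-off.

#' Robust association of deletion status with z-scored expression
#'
#' For every gene in the z-score panel and every region in `calls`, fits
#' `z ~ intercept + deleted + purity` by [rlm_biweight()] on the tumour
#' samples. Samples with missing purity are dropped from the fit (their
#' count is reported per row). Fits with fewer than `min_group` samples in
#' either deletion group, or with a rank-deficient design, are flagged
#' `untestable` and carry no p-value.
#'
#' @param z A `zscore_panel` from [zscore_vs_normal()].
#' @param calls Deletion calls from [call_deletions()] covering every tumour
#'   sample of the panel.
#' @param min_group Minimum samples per deletion group for a testable fit.
#' @return Tibble with one row per (gene, region): `gene_id`, `region_name`,
#'   `tumour_type`, `beta_deletion`, `beta_purity`, `se`, `p_value`,
#'   `n_deleted`, `n_wild_type`, `n_dropped_purity`, `status`
#'   (`"ok"`/`"untestable"`).
#' @seealso [correct_and_filter()]
#' @export
robust_association <- function(z, calls, min_group = 3L) {
  if (!inherits(z, "zscore_panel")) abort("`z` must be a zscore_panel.")
  stop_if_not_df(calls, "calls")
  require_columns(calls, c("sample_id", "region_name", "deleted"), "calls")
  tum_ids <- colnames(z$z)
  missing_calls <- setdiff(tum_ids,
                           unique(calls$sample_id))
  if (length(missing_calls)) {
    abort(sprintf("No deletion call for tumour sample(s): %s.",
                  paste(head(missing_calls, 5), collapse = ", ")))
  }
  purity <- z$samples$purity[match(tum_ids, z$samples$sample_id)]
  fit_one <- function(y, del) {
    ok <- !is.na(purity)
    n_drop <- sum(!ok)
    yk <- y[ok]; dk <- del[ok]; pk <- purity[ok]
    n_del <- sum(dk)
    n_wt <- sum(!dk)
    if (n_del < min_group || n_wt < min_group) {
      return(tibble::tibble(beta_deletion = NA_real_, beta_purity = NA_real_,
                            se = NA_real_, p_value = NA_real_,
                            n_deleted = n_del, n_wild_type = n_wt,
                            n_dropped_purity = n_drop, status = "untestable"))
    }
    X <- cbind(`(Intercept)` = 1, deleted = as.numeric(dk), purity = pk)
    fit <- rlm_biweight(X, yk)
    if (fit$rank_deficient) {
      return(tibble::tibble(beta_deletion = NA_real_, beta_purity = NA_real_,
                            se = NA_real_, p_value = NA_real_,
                            n_deleted = n_del, n_wild_type = n_wt,
                            n_dropped_purity = n_drop, status = "untestable"))
    }
    td <- tidy(fit)
    row <- td[td$term == "deleted", ]
    tibble::tibble(beta_deletion = row$estimate,
                   beta_purity = td$estimate[td$term == "purity"],
                   se = row$std.error, p_value = row$p.value,
                   n_deleted = n_del, n_wild_type = n_wt,
                   n_dropped_purity = n_drop, status = "ok")
  }
  regions <- unique(calls$region_name)
  out <- purrr::map(regions, function(rn) {
    cr <- calls[calls$region_name == rn, , drop = FALSE]
    del <- cr$deleted[match(tum_ids, cr$sample_id)]
    if (anyNA(del)) {
      abort(sprintf("Region '%s': missing deletion call for some tumour samples.", rn))
    }
    res <- purrr::map(rownames(z$z), function(g) fit_one(z$z[g, ], del))
    dplyr::bind_rows(res) |>
      dplyr::mutate(gene_id = rownames(z$z), region_name = rn,
                    tumour_type = z$tumour_type, .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Bonferroni-correct association results and filter to significant genes
#'
#' Adjusts p-values by Bonferroni over the family of tests actually fitted
#' in the run (`m`, by default the number of rows with a finite p-value),
#' assigns a direction from the sign of the deletion coefficient
#' (`up`/`down` when `p_adjusted < alpha`, else `none`), and keeps the
#' significant protein-coding associations.
#'
#' @param results Association tibble from [robust_association()].
#' @param genes Gene tibble with `gene_id` and `protein_coding` (e.g. from
#'   an [expression_panel()]); `NULL` treats every gene as protein-coding.
#' @param alpha Adjusted-p cut-off (default 0.01).
#' @param m Bonferroni family size; default = number of fitted tests.
#' @param keep_all Return all annotated rows instead of only the significant
#'   protein-coding ones.
#' @return The filtered (or, with `keep_all`, full) tibble with added
#'   columns `p_adjusted`, `direction` (`up`/`down`/`none`),
#'   `protein_coding`; the family size is attached as attribute `"m"`.
#' @export
correct_and_filter <- function(results, genes = NULL, alpha = 0.01,
                               m = NULL, keep_all = FALSE) {
  stop_if_not_df(results, "results")
  require_columns(results, c("gene_id", "beta_deletion", "p_value"), "results")
  if (is.null(m)) m <- sum(is.finite(results$p_value))
  out <- results |>
    dplyr::mutate(
      p_adjusted = pmin(1, .data$p_value * .env$m),
      direction = dplyr::case_when(
        !is.finite(.data$p_adjusted) ~ "none",
        .data$p_adjusted < .env$alpha & .data$beta_deletion > 0 ~ "up",
        .data$p_adjusted < .env$alpha & .data$beta_deletion < 0 ~ "down",
        TRUE ~ "none"))
  if (is.null(genes)) {
    out$protein_coding <- TRUE
  } else {
    require_columns(genes, c("gene_id", "protein_coding"), "genes")
    out$protein_coding <- genes$protein_coding[match(out$gene_id, genes$gene_id)]
  }
  attr(out, "m") <- m
  if (keep_all) return(out)
  sig <- dplyr::filter(out, .data$direction != "none", .data$protein_coding)
  attr(sig, "m") <- m
  sig
}

#' Per-exon contrast between deleted and wild-type patients
#'
#' For each exon, computes the difference in mean expression (deleted minus
#' wild-type) with a percentile bootstrap confidence band obtained by
#' resampling samples within each group.
#'
#' @param exon_values Long tibble with columns `exon_index`, `sample_id`,
#'   `value` (z-score or expression).
#' @param labels Tibble with columns `sample_id` and `group`; `group` must
#'   take exactly two values, by default `three_prime_deleted` (first) and
#'   `wild_type` (reference).
#' @param groups Length-2 character vector naming (test, reference) groups.
#' @param B Number of bootstrap resamples.
#' @param conf Confidence level of the percentile band.
#' @param seed Seed for the bootstrap resampling.
#' @return Tibble of class `fx_exon_contrast` with one row per exon:
#'   `exon_index`, `diff`, `lower`, `upper`, `n_deleted`, `n_wild_type`,
#'   `degenerate` (TRUE when a group has a single sample and the band is
#'   meaningless).
#' @examples
#' sim <- simulate_exon_profile(n_exons = 5, deleted_exons = 3,
#'                              n_deleted = 8, n_wild_type = 8, seed = 1)
#' exon_contrast(sim$values, sim$labels, B = 99)
#' @export
exon_contrast <- function(exon_values, labels,
                          groups = c("three_prime_deleted", "wild_type"),
                          B = 1000L, conf = 0.95, seed = 1L) {
  stop_if_not_df(exon_values, "exon_values")
  require_columns(exon_values, c("exon_index", "sample_id", "value"),
                  "exon_values")
  require_columns(labels, c("sample_id", "group"), "labels")
  ids1 <- labels$sample_id[labels$group == groups[1]]
  ids2 <- labels$sample_id[labels$group == groups[2]]
  if (length(ids1) == 0 || length(ids2) == 0) {
    abort(sprintf("Both groups ('%s', '%s') must be non-empty.",
                  groups[1], groups[2]))
  }
  wide <- exon_values |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value") |>
    dplyr::arrange(.data$exon_index)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  m1 <- mat[, as.character(ids1), drop = FALSE]
  m2 <- mat[, as.character(ids2), drop = FALSE]
  diff <- rowMeans(m1) - rowMeans(m2)
  degenerate <- length(ids1) < 2 || length(ids2) < 2
  if (degenerate) {
    lower <- upper <- rep(NA_real_, length(diff))
    warn("A group has a single sample; bootstrap band is degenerate.")
  } else {
    boots <- withr::with_seed(seed, {
      replicate(B, {
        b1 <- m1[, sample.int(ncol(m1), replace = TRUE), drop = FALSE]
        b2 <- m2[, sample.int(ncol(m2), replace = TRUE), drop = FALSE]
        rowMeans(b1) - rowMeans(b2)
      })
    })
    boots <- matrix(boots, nrow = length(diff))
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    qs <- apply(boots, 1, quantile, probs = probs, names = FALSE)
    lower <- qs[1, ]
    upper <- qs[2, ]
  }
  out <- tibble::tibble(exon_index = wide$exon_index, diff = diff,
                        lower = lower, upper = upper,
                        n_deleted = length(ids1),
                        n_wild_type = length(ids2),
                        degenerate = degenerate)
  class(out) <- c("fx_exon_contrast", class(out))
  out
}
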