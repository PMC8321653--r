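# Chromosomal-instability expression signatures (CIN25 / CIN70): score
# samples as the mean z-score of the signature genes, stratify by the
# deletion status of a genomic element, and compare groups with the
# Mann-Whitney U test.

#' Read a signature gene list
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @param name Signature name; defaults to the file name without extension.
#' @return Object of class `signature_definition`: list with `name` and
#'   `genes` (unique, non-empty character vector).
#' @seealso [cin_signature()]
#' @export
read_signature <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  genes <- trimws(readLines(path))
  genes <- genes[nzchar(genes) & !grepl("^#", genes)]
  if (length(genes) == 0) abort(sprintf("Signature file '%s' has no genes.", path))
  if (anyDuplicated(genes)) {
    abort(sprintf("Signature '%s' has duplicate gene(s): %s.", name,
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  structure(list(name = name, genes = genes), class = "signature_definition")
}

#' Load a bundled chromosomal-instability signature
#'
#' Returns the CIN25 (25 genes) or CIN70 (70 genes) signature shipped with
#' the package. The lists are transcriptions of the published
#' chromosomal-instability signatures and can be replaced by any file via
#' [read_signature()].
#'
#' @param name `"CIN25"` or `"CIN70"`.
#' @return A `signature_definition`.
#' @examples
#' length(cin_signature("CIN25")$genes)
#' @export
cin_signature <- function(name = c("CIN25", "CIN70")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      paste0(tolower(name), "_signature_synthetic.txt"),
                      package = "fragilexpress", mustWork = TRUE)
  read_signature(path, name = name)
}

#' Score samples on an expression signature
#'
#' The score of a sample is the mean z-score of the signature genes found in
#' the panel; missing genes are reported, not imputed. Higher scores
#' indicate higher expression of the signature.
#'
#' @param z A `zscore_panel` from [zscore_vs_normal()].
#' @param signature A `signature_definition` (see [read_signature()]).
#' @return Tibble with `sample_id`, `score`, `n_signature_genes_found`;
#'   missing gene symbols attached as attribute `"missing_genes"` and the
#'   aggregation recorded as attribute `"aggregation"` (`"mean_z"`).
#' @export
score_signature <- function(z, signature) {
  if (!inherits(z, "zscore_panel")) abort("`z` must be a zscore_panel.")
  if (!inherits(signature, "signature_definition")) {
    abort("`signature` must be a signature_definition.")
  }
  found <- intersect(signature$genes, rownames(z$z))
  if (length(found) == 0) {
    abort(sprintf("None of the %d genes of signature '%s' are in the panel.",
                  length(signature$genes), signature$name))
  }
  scores <- colMeans(z$z[found, , drop = FALSE])
  out <- tibble::tibble(sample_id = names(scores), score = unname(scores),
                        n_signature_genes_found = length(found))
  attr(out, "missing_genes") <- setdiff(signature$genes, found)
  attr(out, "aggregation") <- "mean_z"
  attr(out, "signature") <- signature$name
  out
}

#' Stratify samples by the deletion status of one element
#'
#' @param calls Deletion calls from [call_deletions()].
#' @param element Region name of the element (e.g. the pseudogene interval).
#' @param samples Optional character vector of samples that must all be
#'   present in the calls (error otherwise); defaults to the samples found.
#' @return Tibble with `sample_id` and `group` (factor
#'   `element_deleted` / `not_deleted`).
#' @export
stratify_by_element <- function(calls, element, samples = NULL) {
  cr <- calls[calls$region_name == element, , drop = FALSE]
  if (nrow(cr) == 0) abort(sprintf("No calls for element region '%s'.", element))
  if (!is.null(samples)) {
    miss <- setdiff(samples, cr$sample_id)
    if (length(miss)) {
      abort(sprintf("Missing deletion call for sample(s): %s.",
                    paste(head(miss, 5), collapse = ", ")))
    }
    cr <- cr[match(samples, cr$sample_id), , drop = FALSE]
  }
  tibble::tibble(sample_id = cr$sample_id,
                 group = factor(ifelse(cr$deleted, "element_deleted",
                                       "not_deleted"),
                                levels = c("element_deleted", "not_deleted")))
}

# Exact two-sided Mann-Whitney p by enumeration of all assignments of the
# pooled ranks to the first group (handles ties through midranks).
mw_exact_p <- function(rk1, rk_all, n1) {
  U_obs <- sum(rk1) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(rk_all), n1)
  U_all <- colSums(matrix(rk_all[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p_le <- mean(U_all <= U_obs + eps)
  p_ge <- mean(U_all >= U_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U comparison of signature scores between groups
#'
#' Compares score distributions between the two groups of a score table.
#' The reported U statistic follows the pinned convention of the
#' first-listed group (`element_deleted` by default). When both groups have
#' at most 7 samples the two-sided p-value is computed by exact enumeration
#' of all rank assignments (ties handled through midranks); larger samples
#' use the tie-corrected normal approximation without continuity
#' correction.
#'
#' @param scores Tibble with columns `score` and `group` (two levels), e.g.
#'   [score_signature()] joined with [stratify_by_element()].
#' @param groups Length-2 character vector: (first-listed, reference)
#'   groups.
#' @return One-row tibble: `statistic` (U of the first group), `p_value`,
#'   `method` (`"exact"` or `"normal"`), `n1`, `n2`.
#' @examples
#' sc <- tibble::tibble(score = c(1, 2, 3, 4, 5, 6),
#'                      group = rep(c("element_deleted", "not_deleted"),
#'                                  each = 3))
#' compare_groups(sc)
#' @export
compare_groups <- function(scores,
                           groups = c("element_deleted", "not_deleted")) {
  stop_if_not_df(scores, "scores")
  require_columns(scores, c("score", "group"), "scores")
  x <- scores$score[scores$group == groups[1]]
  y <- scores$score[scores$group == groups[2]]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) {
    abort(sprintf("Both groups ('%s', '%s') must be non-empty.",
                  groups[1], groups[2]))
  }
  rk <- rank(c(x, y))
  rk1 <- rk[seq_len(n1)]
  U <- sum(rk1) - n1 * (n1 + 1) / 2
  if (n1 <= 7 && n2 <= 7) {
    p <- mw_exact_p(rk1, rk, n1)
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1 # all observations tied
    } else {
      zstat <- (U - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(zstat))
    }
    method <- "normal"
  }
  tibble::tibble(statistic = U, p_value = p, method = method,
                 n1 = n1, n2 = n2)
}
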