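# Z-scoring against normals, the biweight robust fit, Bonferroni filtering
# and the per-exon contrast.

test_that("zscore_vs_normal reproduces hand-computed z-scores", {
  # normals {1, 3}: mu = 2, sd = sqrt(2) (denominator n - 1); tumour 4 -> z = sqrt(2)
  panel <- panel_from_values(tumour = matrix(c(4, 2), 1),
                             normal = matrix(c(1, 3), 1))
  z <- zscore_vs_normal(panel, "TT", log_transform = FALSE)
  expect_equal(unname(z$z["g1", "t01"]), sqrt(2), tolerance = 1e-12)
  # tumour equal to the normal mean -> z = 0
  expect_equal(unname(z$z["g1", "t02"]), 0, tolerance = 1e-12)
  expect_equal(z$reference$mu, 2)
  expect_equal(z$reference$sd, sqrt(2))
})

test_that("constant genes are dropped with a report and few normals error", {
  panel <- panel_from_values(tumour = matrix(c(4, 5, 2, 2), 2),
                             normal = matrix(c(1, 2, 3, 2), 2))
  z <- zscore_vs_normal(panel, "TT", log_transform = FALSE)
  expect_equal(z$dropped, "g2")
  expect_equal(rownames(z$z), "g1")

  one_normal <- panel_from_values(tumour = matrix(c(4, 2), 1),
                                  normal = matrix(1, 1))
  expect_error(zscore_vs_normal(one_normal, "TT"), ">= 2 normal")
})

test_that("z-scoring the normals themselves gives mean 0 and SD 1", {
  withr::with_seed(3, {
    normal <- matrix(rexp(20 * 8, 1 / 50), 20, 8)
    tumour <- matrix(rexp(20 * 5, 1 / 50), 20, 5)
  })
  panel <- panel_from_values(tumour, normal)
  for (log_transform in c(TRUE, FALSE)) {
    z <- zscore_vs_normal(panel, "TT", log_transform = log_transform)
    xn <- panel$values[z$reference$gene_id,
                       !panel$samples$is_tumour, drop = FALSE]
    if (log_transform) xn <- log1p(xn)
    zn <- (xn - z$reference$mu) / z$reference$sd
    expect_lt(max(abs(rowMeans(zn))), 1e-12)
    expect_lt(max(abs(apply(zn, 1, sd) - 1)), 1e-12)
  }
})

test_that("biweight IRLS agrees with the OLS oracle and MASS on clean data", {
  withr::with_seed(10, {
    n <- 200
    X <- cbind(1, rbinom(n, 1, 0.3), runif(n))
    y <- 0.4 + 0.8 * X[, 2] + 0.3 * X[, 3] + rnorm(n, sd = 0.01)
  })
  fit <- rlm_biweight(X, y)
  ols <- lm.fit(X, y)$coefficients
  expect_lt(max(abs(coef(fit) - ols)), 1e-3)
  mass <- MASS::rlm(X, y, psi = MASS::psi.bisquare, maxit = 100)
  expect_lt(max(abs(coef(fit) - coef(mass))), 1e-4)
  expect_true(fit$converged)
  td <- tidy(fit)
  expect_equal(td$estimate, unname(coef(fit)))
  expect_true(all(td$p.value > 0 & td$p.value <= 1))
  expect_equal(glance(fit)$df.residual, n - 3)
})

test_that("the robust fit resists gross outliers better than OLS", {
  wins <- withr::with_seed(99, {
    vapply(1:100, function(i) {
      n <- 100
      x <- rbinom(n, 1, 0.4)
      y <- 1 + 0.5 * x + rnorm(n)
      out_idx <- sample(which(x == 1), ceiling(0.1 * n))
      y[out_idx] <- y[out_idx] * 10
      X <- cbind(1, x)
      rob <- coef(rlm_biweight(X, y))[2]
      ols <- lm.fit(X, y)$coefficients[2]
      abs(rob - 0.5) < abs(ols - 0.5)
    }, logical(1))
  })
  expect_gte(mean(wins), 0.9)
})

test_that("rank-deficient designs are flagged instead of fitted", {
  X <- cbind(1, rep(1, 10), runif(10)) # all samples 'deleted'
  fit <- rlm_biweight(X, rnorm(10))
  expect_true(fit$rank_deficient)
  expect_true(all(is.na(coef(fit))))
})

test_that("robust_association is order-invariant and flips with the indicator", {
  sim <- simulate_cohort(cohort_config(seed = 5, n_tumours = 60,
                                       n_normals = 10),
                         demo_annotation(n_genes = 4))
  z <- zscore_vs_normal(sim$panel, "TYPE_A")
  tum <- colnames(z$z)
  calls <- tibble::tibble(
    sample_id = tum, region_name = "FS_A",
    deleted = sim$truth$deletions$deleted[match(tum, sim$truth$deletions$sample_id)])
  res <- robust_association(z, calls)
  # permuted call order gives identical results
  res_perm <- robust_association(z, calls[sample(nrow(calls)), ])
  expect_equal(as.data.frame(res), as.data.frame(res_perm))
  # flipped indicator: beta changes sign, p unchanged
  flipped <- dplyr::mutate(calls, deleted = !deleted)
  res_flip <- robust_association(z, flipped)
  expect_equal(res_flip$beta_deletion, -res$beta_deletion, tolerance = 1e-6)
  expect_equal(res_flip$p_value, res$p_value, tolerance = 1e-6)
})

test_that("samples with missing purity are dropped and counted", {
  sim <- simulate_cohort(cohort_config(seed = 8, n_tumours = 40,
                                       n_normals = 8),
                         demo_annotation(n_genes = 3))
  panel <- sim$panel
  panel$samples$purity[panel$samples$sample_id %in% c("T0001", "T0002")] <- NA
  z <- zscore_vs_normal(panel, "TYPE_A")
  calls <- tibble::tibble(
    sample_id = colnames(z$z), region_name = "FS_A",
    deleted = sim$truth$deletions$deleted[match(colnames(z$z),
                                                sim$truth$deletions$sample_id)])
  res <- robust_association(z, calls)
  expect_true(all(res$n_dropped_purity == 2))
  expect_true(all(res$n_deleted + res$n_wild_type == 38))
})

test_that("groups below the floor are untestable, not fitted", {
  z <- structure(list(
    z = matrix(rnorm(40), 2, 20,
               dimnames = list(c("g1", "g2"), sprintf("t%02d", 1:20))),
    samples = tibble::tibble(sample_id = sprintf("t%02d", 1:20),
                             tumour_type = "TT", is_tumour = TRUE,
                             purity = runif(20, 0.5, 1)),
    tumour_type = "TT", log_transform = TRUE, dropped = character(),
    reference = NULL), class = "zscore_panel")
  calls <- tibble::tibble(sample_id = sprintf("t%02d", 1:20),
                          region_name = "R", deleted = c(TRUE, TRUE,
                                                         rep(FALSE, 18)))
  res <- robust_association(z, calls)
  expect_true(all(res$status == "untestable"))
  expect_true(all(is.na(res$p_value)))
})

test_that("correct_and_filter applies Bonferroni, direction and coding filter", {
  results <- tibble::tibble(
    gene_id = c("pc_up", "pc_flat", "nc_up", "pc_down"),
    region_name = "R", tumour_type = "TT",
    beta_deletion = c(2, 0.1, 3, -2),
    p_value = c(0.0005, 0.5, 1e-6, 0.0001), status = "ok")
  genes <- tibble::tibble(gene_id = results$gene_id,
                          protein_coding = c(TRUE, TRUE, FALSE, TRUE))
  full <- correct_and_filter(results, genes, m = 10, keep_all = TRUE)
  expect_equal(full$p_adjusted[1], 0.005)         # 10 x 0.0005
  expect_equal(full$p_adjusted[2], 1)             # capped at 1
  expect_equal(full$direction,
               c("up", "none", "up", "down"))
  sig <- correct_and_filter(results, genes, m = 10)
  # the non-coding gene is excluded despite p_adjusted = 1e-5
  expect_setequal(sig$gene_id, c("pc_up", "pc_down"))
  expect_equal(attr(sig, "m"), 10)

  # adjusted p never below raw p; significance non-increasing in m
  expect_true(all(full$p_adjusted >= full$p_value))
  n_sig <- vapply(c(1, 10, 100, 1000), function(m) {
    nrow(correct_and_filter(results, genes, m = m))
  }, numeric(1))
  expect_true(all(diff(n_sig) <= 0))
})

test_that("exon_contrast is near zero for identical groups and flags singletons", {
  withr::with_seed(2, {
    vals <- tibble::tibble(
      exon_index = rep(1:5, 10),
      sample_id = rep(sprintf("s%02d", 1:10), each = 5),
      value = rnorm(50))
  })
  labels <- tibble::tibble(sample_id = sprintf("s%02d", 1:10),
                           group = rep(c("three_prime_deleted", "wild_type"),
                                       5))
  # same generating distribution: differences small, band covers 0 mostly
  ctr <- exon_contrast(vals, labels, B = 200, seed = 4)
  expect_equal(nrow(ctr), 5)
  expect_true(all(abs(ctr$diff) < 2))
  expect_false(any(ctr$degenerate))

  lab1 <- tibble::tibble(sample_id = sprintf("s%02d", 1:10),
                         group = c("three_prime_deleted",
                                   rep("wild_type", 9)))
  expect_warning(ctr1 <- exon_contrast(vals, lab1, B = 50),
                 "degenerate")
  expect_true(all(ctr1$degenerate))
  expect_true(all(is.na(ctr1$lower)))

  empty <- tibble::tibble(sample_id = sprintf("s%02d", 1:10),
                          group = "wild_type")
  expect_error(exon_contrast(vals, empty), "non-empty")
})

test_that("exon_contrast recovers the planted breakpoint sign pattern", {
  matches <- vapply(1:20, function(s) {
    sim <- simulate_exon_profile(seed = s)
    ctr <- exon_contrast(sim$values, sim$labels, B = 50, seed = s)
    planted <- ifelse(sim$truth$direction == "up", 1, -1)
    sum(sign(ctr$diff) == planted)
  }, numeric(1))
  expect_gte(mean(matches), 9) # out of 11 exons
  expect_gte(min(matches), 9)
})
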