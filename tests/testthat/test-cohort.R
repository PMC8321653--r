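# The synthetic cohort generator: determinism, planted-truth bookkeeping,
# closed-form recovery of planted effects, and IO round-trips.

test_that("cohort_config validates fields and lists all problems at once", {
  expect_s3_class(cohort_config(), "cohort_config")
  err <- tryCatch(cohort_config(deletion_prevalence = 1.5, n_normals = 1,
                                expression_noise_sd = -1),
                  error = conditionMessage)
  expect_match(err, "deletion_prevalence")
  expect_match(err, "n_normals")
  expect_match(err, "expression_noise_sd")
  expect_error(cohort_config(deleted_seg_mean_range = c(-0.2, -0.05)),
               "below -0.1")
})

test_that("identical seed and config give bit-identical cohorts", {
  ann <- demo_annotation(n_genes = 5)
  cfg <- cohort_config(seed = 42, n_tumours = 30, n_normals = 5)
  a <- simulate_cohort(cfg, ann)
  b <- simulate_cohort(cfg, ann)
  expect_identical(a$segments, b$segments)
  expect_identical(a$panel$values, b$panel$values)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(cohort_config(seed = 43, n_tumours = 30,
                                     n_normals = 5), ann)
  expect_false(identical(a$panel$values, c$panel$values))
})

test_that("deletion counts follow the prevalence and truth is coherent", {
  ann <- demo_annotation(n_genes = 3)
  sim <- simulate_cohort(cohort_config(seed = 1, n_tumours = 100,
                                       n_normals = 5,
                                       deletion_prevalence = 0.5), ann)
  n_del <- sum(sim$truth$deletions$deleted)
  expect_gte(n_del, 30)
  expect_lte(n_del, 70)
  # every planted deleted sub-interval overlaps its fragile site
  del <- sim$truth$deletions[sim$truth$deletions$deleted, ]
  site <- ann$sites[1, ]
  expect_true(all(del$del_start >= site$start & del$del_end <= site$end))
  expect_true(all(del$del_end > del$del_start))
  # deleted samples carry a qualifying segment over the site; others none
  calls <- call_deletions(filter_segments(sim$segments), ann$sites,
                          samples = sim$truth$deletions$sample_id)
  joined <- dplyr::left_join(sim$truth$deletions, calls,
                             by = "sample_id")
  expect_equal(joined$deleted.x, joined$deleted.y)
})

test_that("zero effect size yields direction none everywhere", {
  ann <- demo_annotation(n_genes = 4)
  eff <- tibble::tibble(gene_id = "G001", site = "FS_A", z_shift = 0)
  sim <- simulate_cohort(cohort_config(seed = 2, n_tumours = 20,
                                       n_normals = 4, effect_sizes = eff),
                         ann)
  expect_true(all(sim$truth$genes$direction == "none"))
})

test_that("a planted z-shift is recovered at its closed-form value", {
  ann <- demo_annotation(n_genes = 2)
  diffs <- vapply(1:20, function(s) {
    cfg <- cohort_config(seed = s, n_tumours = 100, n_normals = 40,
                         purity_shape = NULL) # purity = 1
    sim <- simulate_cohort(cfg, ann)
    z <- zscore_vs_normal(sim$panel, "TYPE_A")
    del <- sim$truth$deletions$deleted[match(colnames(z$z),
                                             sim$truth$deletions$sample_id)]
    mean(z$z["G001", del]) - mean(z$z["G001", !del])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 1.5), 3 * se)
})

test_that("null cohorts keep deleted and wild-type expression exchangeable", {
  ann <- demo_annotation(n_genes = 2)
  eff <- tibble::tibble(gene_id = "G001", site = "FS_A", z_shift = 0)
  rejections <- vapply(1:30, function(s) {
    cfg <- cohort_config(seed = s, n_tumours = 60, n_normals = 10,
                         effect_sizes = eff, purity_shape = NULL)
    sim <- simulate_cohort(cfg, ann)
    del <- sim$truth$deletions$deleted
    x <- log1p(sim$panel$values["G001", sim$truth$deletions$sample_id])
    suppressWarnings(stats::wilcox.test(x[del], x[!del])$p.value) < 0.05
  }, logical(1))
  # nominal size ~0.05: allow binomial slack over 30 seeds
  expect_lte(mean(rejections), 0.2)
})

test_that("purity dilutes the planted effect", {
  ann <- demo_annotation(n_genes = 2)
  diffs <- vapply(1:10, function(s) {
    cfg <- cohort_config(seed = s, n_tumours = 150, n_normals = 40,
                         purity_shape = c(2, 5)) # low purity, mean 2/7
    sim <- simulate_cohort(cfg, ann)
    z <- zscore_vs_normal(sim$panel, "TYPE_A")
    del <- sim$truth$deletions$deleted[match(colnames(z$z),
                                             sim$truth$deletions$sample_id)]
    mean(z$z["G001", del]) - mean(z$z["G001", !del])
  }, numeric(1))
  # diluted towards 1.5 x E[purity] ~ 0.43, far below the undiluted 1.5
  expect_lt(mean(diffs), 1.0)
  expect_gt(mean(diffs), 0.1)
})

test_that("simulate_exon_profile plants the advertised truth", {
  sim <- simulate_exon_profile(n_exons = 11, deleted_exons = 6:8, seed = 9)
  expect_equal(sim$truth$direction,
               c(rep("up", 5), rep("down", 3), rep("up", 2), "up")[1:11])
  expect_error(simulate_exon_profile(n_exons = 3, deleted_exons = 1:3),
               "intact")
  expect_error(simulate_exon_profile(n_exons = 3, deleted_exons = 4),
               "out of range")
  flat <- simulate_exon_profile(shift = 0, seed = 9)
  expect_true(all(flat$truth$direction == "none"))
})

test_that("simulated coverage matches its Poisson expectation", {
  ann <- demo_annotation(n_genes = 1)
  ratios <- vapply(1:10, function(s) {
    tracks <- simulate_coverage(ann$exons, ann$elements, drop_factor = 0.3,
                                n_tracks = 14, mu = 100, seed = s)
    raw <- exon_signal(tracks, ann$exons)
    mean(raw$E[raw$exon_index > 8]) / mean(raw$E[raw$exon_index <= 8])
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.3), 3 * se + 0.01)
})

test_that("a generated cohort round-trips through the format writers", {
  ann <- demo_annotation(n_genes = 3)
  sim <- simulate_cohort(cohort_config(seed = 4, n_tumours = 10,
                                       n_normals = 3), ann)
  seg_path <- tempfile(fileext = ".seg")
  write_seg(sim$segments, seg_path)
  back <- read_seg(seg_path)
  expect_equal(as.data.frame(back), as.data.frame(sim$segments),
               tolerance = 1e-12)
  pm <- tempfile(); ps <- tempfile()
  write_expression(sim$panel, pm, ps)
  panel_back <- read_expression(pm, ps)
  expect_equal(panel_back$values, sim$panel$values, tolerance = 1e-12)
})
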