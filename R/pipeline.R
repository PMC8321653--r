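# Pipeline orchestration: one config drives deletion calling, z-scoring,
# robust association, the optional exon contrast, instability-signature
# comparison and the TT-seq exon profile, with a run log and a
# machine-readable provenance record. Re-running with the same config and
# seeds reproduces every output bit-exactly.

default_run_config <- function() {
  list(
    out_dir = "fragilexpress_run",
    seg = NULL, sites_bed = NULL,
    expression_matrix = NULL, expression_metadata = NULL, genes_tsv = NULL,
    element_bed = NULL, exons_bed = NULL, tracks_dir = NULL,
    exon_values_tsv = NULL, exon_labels_tsv = NULL,
    signature = "CIN25", signature_file = NULL,
    threshold = -0.1, alpha = 0.01, log_transform = TRUE,
    min_group = 3, bootstrap_B = 200, seed = 1,
    stages = list(associate = TRUE, exon_contrast = FALSE, cin = FALSE,
                  ttseq = FALSE))
}

#' Read a pipeline run configuration from YAML
#'
#' Unset fields fall back to the package defaults (segment filter threshold
#' -0.1, significance cut-off alpha 0.01 on Bonferroni-adjusted p-values,
#' log1p transform on).
#'
#' @param path Path to a YAML config file.
#' @return A named list of class `run_config`.
#' @seealso [run_pipeline()]
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  # paths in the config are relative to the config file
  base <- dirname(normalizePath(path))
  path_fields <- c("seg", "sites_bed", "expression_matrix",
                   "expression_metadata", "genes_tsv", "element_bed",
                   "exons_bed", "tracks_dir", "exon_values_tsv",
                   "exon_labels_tsv", "signature_file", "out_dir")
  for (f in path_fields) {
    if (!is.null(cfg[[f]]) && !grepl("^/", cfg[[f]])) {
      cfg[[f]] <- file.path(base, cfg[[f]])
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

validate_run_config <- function(cfg) {
  problems <- character()
  need <- function(field, stage) {
    if (is.null(cfg[[field]])) {
      problems <<- c(problems,
                     sprintf("`%s` is required for the %s stage", field, stage))
    } else if (!file.exists(cfg[[field]])) {
      problems <<- c(problems,
                     sprintf("`%s` does not exist: %s", field, cfg[[field]]))
    }
  }
  need("seg", "call-deletions")
  need("sites_bed", "call-deletions")
  if (isTRUE(cfg$stages$associate)) {
    need("expression_matrix", "associate")
    need("expression_metadata", "associate")
  }
  if (isTRUE(cfg$stages$exon_contrast)) {
    need("exon_values_tsv", "exon-contrast")
    need("exon_labels_tsv", "exon-contrast")
  }
  if (isTRUE(cfg$stages$cin)) need("element_bed", "cin")
  if (isTRUE(cfg$stages$ttseq)) {
    need("exons_bed", "ttseq")
    need("element_bed", "ttseq")
    need("tracks_dir", "ttseq")
  }
  if (!is.numeric(cfg$threshold)) problems <- c(problems, "`threshold` must be numeric")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    problems <- c(problems, "`alpha` must lie in (0, 1)")
  }
  if (length(problems)) {
    abort(paste0("Invalid run configuration:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  invisible(cfg)
}

#' Run the full deletion-expression pipeline
#'
#' Executes the enabled stages in order — deletion calling from filtered
#' segments, per-type z-scoring against normals, robust association with
#' Bonferroni correction, optional exon contrast, optional
#' instability-signature comparison, optional TT-seq exon profile — writing
#' TSV outputs, a run log with row counts per stage, a plain-text summary
#' and a provenance JSON (config, package version, seeds) into
#' `config$out_dir`. A failing stage aborts with an error naming the stage.
#'
#' @param config A `run_config` list, or the path to a YAML config file
#'   (see [read_run_config()]).
#' @param verbose Also echo the log to stderr.
#' @return Invisibly, a named list with the in-memory results of each
#'   executed stage.
#' @examples
#' \donttest{
#' fx <- make_fixtures(file.path(tempdir(), "fxdemo"), seed = 7)
#' res <- run_pipeline(fx$config)
#' res$significant
#' }
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  results <- list()

  # --- call-deletions -------------------------------------------------
  segments <- stage("read-seg", read_seg(cfg$seg))
  sites <- stage("read-regions", read_bed(cfg$sites_bed, kind = "fragile_site"))
  say("read %d segments, %d fragile-site regions", nrow(segments), nrow(sites))
  filtered <- filter_segments(segments, threshold = cfg$threshold)
  say("segment filter (< %g): %d of %d segments retained", cfg$threshold,
      nrow(filtered), nrow(segments))
  panel <- NULL
  if (isTRUE(cfg$stages$associate) || isTRUE(cfg$stages$cin)) {
    panel <- stage("read-expression",
                   read_expression(cfg$expression_matrix,
                                   cfg$expression_metadata, cfg$genes_tsv))
    say("expression panel: %d genes x %d samples", nrow(panel$values),
        ncol(panel$values))
  }
  tum_ids <- if (!is.null(panel)) {
    panel$samples$sample_id[panel$samples$is_tumour]
  } else {
    unique(segments$sample_id)
  }
  call_regions <- sites
  if (!is.null(cfg$element_bed)) {
    element <- stage("read-regions", read_bed(cfg$element_bed, kind = "element"))
    call_regions <- dplyr::bind_rows(sites, element)
  }
  calls <- stage("call-deletions",
                 call_deletions(filtered, call_regions, samples = tum_ids))
  readr::write_tsv(calls, file.path(cfg$out_dir, "calls.tsv"))
  say("deletion calls: %d (sample, region) pairs, %d deleted",
      nrow(calls), sum(calls$deleted))
  results$calls <- calls

  # --- z-score + associate -------------------------------------------
  if (isTRUE(cfg$stages$associate)) {
    types <- unique(panel$samples$tumour_type[panel$samples$is_tumour])
    assoc <- purrr::map(types, function(tt) {
      z <- stage("zscore", zscore_vs_normal(panel, tt,
                                            log_transform = cfg$log_transform))
      say("z-score [%s]: %d genes retained, %d dropped for zero normal SD",
          tt, nrow(z$z), length(z$dropped))
      site_calls <- calls[calls$region_name %in% sites$name, , drop = FALSE]
      site_calls <- site_calls[site_calls$sample_id %in% colnames(z$z), ,
                               drop = FALSE]
      stage("associate", robust_association(z, site_calls,
                                            min_group = cfg$min_group))
    })
    assoc <- dplyr::bind_rows(assoc)
    annotated <- correct_and_filter(assoc, panel$genes, alpha = cfg$alpha,
                                    keep_all = TRUE)
    sig <- dplyr::filter(annotated, .data$direction != "none",
                         .data$protein_coding)
    m <- attr(annotated, "m")
    say("association: %d tests fitted (Bonferroni family m = %d), %d dropped for missing purity, %d significant at adjusted p < %g",
        sum(assoc$status == "ok"), m, max(assoc$n_dropped_purity), nrow(sig),
        cfg$alpha)
    readr::write_tsv(annotated, file.path(cfg$out_dir, "associations.tsv"))
    readr::write_tsv(sig, file.path(cfg$out_dir, "significant.tsv"))
    results$associations <- annotated
    results$significant <- sig
    results$family_size <- m
  }

  # --- exon contrast --------------------------------------------------
  if (isTRUE(cfg$stages$exon_contrast)) {
    exon_values <- stage("exon-contrast",
                         readr::read_tsv(cfg$exon_values_tsv,
                                         show_col_types = FALSE,
                                         progress = FALSE))
    exon_labels <- readr::read_tsv(cfg$exon_labels_tsv,
                                   show_col_types = FALSE, progress = FALSE)
    contrast <- stage("exon-contrast",
                      exon_contrast(exon_values, exon_labels,
                                    B = cfg$bootstrap_B, seed = cfg$seed))
    readr::write_tsv(contrast, file.path(cfg$out_dir, "exon_contrast.tsv"))
    say("exon contrast: %d exons, %d vs %d samples", nrow(contrast),
        contrast$n_deleted[1], contrast$n_wild_type[1])
    results$exon_contrast <- contrast
  }

  # --- cin ------------------------------------------------------------
  if (isTRUE(cfg$stages$cin)) {
    signature <- if (!is.null(cfg$signature_file)) {
      stage("cin", read_signature(cfg$signature_file))
    } else {
      stage("cin", cin_signature(cfg$signature))
    }
    element_name <- read_bed(cfg$element_bed, kind = "element")$name[1]
    tt <- unique(panel$samples$tumour_type[panel$samples$is_tumour])[1]
    z <- stage("cin", zscore_vs_normal(panel, tt,
                                       log_transform = cfg$log_transform))
    scores <- stage("cin", score_signature(z, signature))
    groups <- stage("cin", stratify_by_element(calls, element_name,
                                               samples = scores$sample_id))
    scored <- dplyr::left_join(scores, groups, by = "sample_id")
    test <- stage("cin", compare_groups(scored))
    readr::write_tsv(scored, file.path(cfg$out_dir, "cin_scores.tsv"))
    readr::write_tsv(test, file.path(cfg$out_dir, "cin_test.tsv"))
    say("cin [%s]: %d scored samples (%d signature genes found), U = %g, p = %.3g",
        signature$name, nrow(scored), scores$n_signature_genes_found[1],
        test$statistic, test$p_value)
    results$cin_scores <- scored
    results$cin_test <- test
  }

  # --- ttseq ----------------------------------------------------------
  if (isTRUE(cfg$stages$ttseq)) {
    exons <- stage("ttseq", read_bed(cfg$exons_bed, kind = "exon"))
    element <- read_bed(cfg$element_bed, kind = "element")
    track_files <- sort(list.files(cfg$tracks_dir, pattern = "\\.bedgraph$",
                                   full.names = TRUE))
    if (length(track_files) == 0) {
      abort(sprintf("Pipeline stage 'ttseq' failed: no .bedgraph files in %s",
                    cfg$tracks_dir))
    }
    region <- list(chrom = exons$chrom[1], start = min(exons$start),
                   end = max(exons$end))
    tracks <- purrr::map(track_files, read_bedgraph, region = region)
    profile <- stage("ttseq", ttseq_exon_profile(tracks, exons))
    o <- exon_transcription_order(exons)
    k <- sum(exons$end[o] <= element$start[1])
    drop_stat <- post_element_drop(profile, k)
    readr::write_tsv(profile, file.path(cfg$out_dir, "ttseq_profile.tsv"))
    say("ttseq: %d tracks, %d exons, post-element drop statistic %.4f (element after exon %d)",
        length(tracks), nrow(profile), drop_stat, k)
    results$ttseq_profile <- profile
    results$ttseq_drop <- drop_stat
  }

  # --- reports --------------------------------------------------------
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  writeLines(c("fragilexpress pipeline summary", "", log_lines),
             file.path(cfg$out_dir, "summary.txt"))
  provenance <- list(
    package = "fragilexpress",
    version = as.character(utils::packageVersion("fragilexpress")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "stages")],
    stages = cfg$stages)
  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(results)
}

#' Write a complete miniature demo dataset
#'
#' Generates a synthetic cohort under the default study conditions, an
#' exon-level breakpoint profile, and coverage tracks with a post-element
#' drop, writes everything through the package's format writers (SEG, BED,
#' TSV, bedGraph), and emits a ready-to-run YAML pipeline config. The last
#' background gene is flagged non-protein-coding so the coding filter is
#' exercised.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed governing all generated data.
#' @param config A [cohort_config()]; its seed is overridden by `seed`.
#' @return Invisibly, a named list of the written file paths (element
#'   `config` is the YAML file, ready for [run_pipeline()]).
#' @export
make_fixtures <- function(dir, seed = 1L, config = cohort_config()) {
  config$seed <- as.integer(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- demo_annotation()
  sim <- simulate_cohort(config, ann)
  paths <- list(
    seg = file.path(dir, "cohort.seg"),
    sites_bed = file.path(dir, "sites.bed"),
    genes_bed = file.path(dir, "genes.bed"),
    exons_bed = file.path(dir, "exons.bed"),
    element_bed = file.path(dir, "element.bed"),
    portions_bed = file.path(dir, "portions.bed"),
    expression_matrix = file.path(dir, "expression.tsv"),
    expression_metadata = file.path(dir, "samples.tsv"),
    genes_tsv = file.path(dir, "genes_meta.tsv"),
    truth_deletions = file.path(dir, "truth_deletions.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    exon_values_tsv = file.path(dir, "exon_values.tsv"),
    exon_labels_tsv = file.path(dir, "exon_labels.tsv"),
    tracks_dir = file.path(dir, "tracks"),
    config = file.path(dir, "config.yaml"))
  write_seg(sim$segments, paths$seg)
  write_bed(ann$sites, paths$sites_bed)
  write_bed(ann$genes, paths$genes_bed)
  write_bed(ann$exons, paths$exons_bed)
  write_bed(ann$elements, paths$element_bed)
  write_bed(ann$portions, paths$portions_bed)
  sim$panel$genes$protein_coding[nrow(sim$panel$genes)] <- FALSE
  write_expression(sim$panel, paths$expression_matrix,
                   paths$expression_metadata, paths$genes_tsv)
  readr::write_tsv(sim$truth$deletions, paths$truth_deletions)
  readr::write_tsv(sim$truth$genes, paths$truth_genes)
  exon_sim <- simulate_exon_profile(seed = derive_seed(seed, 1))
  readr::write_tsv(exon_sim$values, paths$exon_values_tsv)
  readr::write_tsv(exon_sim$labels, paths$exon_labels_tsv)
  dir.create(paths$tracks_dir, showWarnings = FALSE)
  tracks <- simulate_coverage(ann$exons, ann$elements, drop_factor = 0.3,
                              seed = derive_seed(seed, 2))
  purrr::walk(tracks, function(tr) {
    write_bedgraph(tr, file.path(paths$tracks_dir,
                                 paste0(tr$sample_id, ".bedgraph")))
  })
  cfg <- list(seg = "cohort.seg", sites_bed = "sites.bed",
              expression_matrix = "expression.tsv",
              expression_metadata = "samples.tsv",
              genes_tsv = "genes_meta.tsv",
              element_bed = "element.bed", exons_bed = "exons.bed",
              tracks_dir = "tracks",
              exon_values_tsv = "exon_values.tsv",
              exon_labels_tsv = "exon_labels.tsv",
              signature = "CIN25", threshold = -0.1, alpha = 0.01,
              log_transform = TRUE, seed = as.integer(seed),
              out_dir = "results",
              stages = list(associate = TRUE, exon_contrast = TRUE,
                            cin = TRUE, ttseq = TRUE))
  yaml::write_yaml(cfg, paths$config)
  invisible(paths)
}
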