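# Synthetic cohorts with the statistical structure the analysis assumes:
# planted fragile-site deletions, cis expression effects of stated sign and
# size diluted by tumour purity, normal-tissue reference samples, exon-level
# breakpoint structure, and coverage tracks with a post-element signal drop.

#' Demo genome annotation for synthetic cohorts
#'
#' One fragile site on chr4 containing a compact 11-exon resident gene with
#' an antisense element in the intron between exons 8 and 9 (mirroring a
#' pseudogene inside a host gene), plus background genes on chr5. Also
#' returns the 5'/central/3' portions of the resident gene (the central
#' portion contains the element).
#'
#' @param n_genes Total number of genes (>= 1; gene 1 is the fragile-site
#'   resident gene).
#' @return List of region tibbles: `sites`, `genes`, `exons`, `elements`,
#'   `portions`.
#' @examples
#' names(demo_annotation())
#' @export
demo_annotation <- function(n_genes = 20) {
  if (n_genes < 1) abort("`n_genes` must be >= 1.")
  sites <- tibble::tibble(chrom = "chr4", start = 1e6, end = 2.5e6,
                          name = "FS_A", strand = ".", kind = "fragile_site")
  gene_start <- 1.6e6
  exon_starts <- gene_start + (0:10) * 3600
  exons <- tibble::tibble(chrom = "chr4", start = exon_starts,
                          end = exon_starts + 300,
                          name = sprintf("G001_exon%02d", 1:11),
                          strand = "+", kind = "exon")
  gene_end <- max(exons$end)
  genes <- tibble::tibble(chrom = "chr4", start = gene_start, end = gene_end,
                          name = "G001", strand = "+", kind = "gene")
  if (n_genes > 1) {
    # background genes borrow instability-signature symbols so the demo
    # cohort can exercise CIN scoring; extras get generic names
    bg_names <- unique(c(cin_signature("CIN25")$genes,
                         sprintf("G%03d", 2:max(2, n_genes))))[seq_len(n_genes - 1)]
    bg_start <- 1e6 + (seq_len(n_genes - 1) - 1) * 2e5
    genes <- dplyr::bind_rows(genes, tibble::tibble(
      chrom = "chr5", start = bg_start, end = bg_start + 5e4,
      name = bg_names, strand = "+", kind = "gene"))
  }
  # antisense element in the intron between exon 8 and exon 9
  elements <- tibble::tibble(chrom = "chr4",
                             start = exons$end[8] + 1500,
                             end = exons$end[8] + 1700,
                             name = "PSG1", strand = "-", kind = "element")
  portions <- tibble::tibble(
    chrom = "chr4",
    start = c(gene_start, exons$start[6], exons$start[9]),
    end = c(exons$start[6], exons$start[9], gene_end),
    name = c("five_prime", "central", "three_prime"),
    strand = "+", kind = "gene")
  list(sites = sites, genes = genes, exons = exons, elements = elements,
       portions = portions)
}

#' Configuration for a synthetic cohort
#'
#' Collects and validates the generator parameters. Defaults define the
#' standard study conditions used throughout the package's tests: 200
#' tumours and 50 normals of one tumour type, fragile-site deletion
#' prevalence 0.3, a single resident gene planted with a +1.5 z-shift,
#' purity drawn from Beta(5, 2) (mean ~0.71, typical of bulk tumour
#' estimates) multiplying the planted effect, unit expression noise, and
#' deletion segment values drawn uniformly from [-1.0, -0.3] — safely below
#' the -0.1 segment filter.
#'
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   same seed and config.
#' @param n_tumours,n_normals Cohort sizes (`n_normals >= 2`; z-scores need
#'   an SD).
#' @param tumour_types Character vector of type labels, cycled over
#'   samples.
#' @param deletion_prevalence Per-site deletion probability in `[0, 1]`
#'   (recycled over sites).
#' @param effect_sizes `NULL` (default: the first gene residing in each
#'   site gets `default_z_shift`) or a tibble with columns `gene_id`,
#'   `site`, `z_shift`.
#' @param default_z_shift Planted z-shift used when `effect_sizes` is
#'   `NULL`.
#' @param purity_shape Length-2 numeric `(alpha, beta)` of the Beta purity
#'   law (both > 0), or `NULL` for purity identically 1.
#' @param expression_noise_sd Gaussian noise SD on the log1p(FPKM) scale
#'   (> 0).
#' @param baseline_log_fpkm Per-gene baseline on the log1p(FPKM) scale
#'   (scalar recycled).
#' @param deleted_seg_mean_range Interval (entirely below -0.1) from which
#'   deletion segment values are drawn uniformly.
#' @param neutral_seg_mean_sd SD of near-zero background segment values.
#' @param deletion_span_frac Range of the deleted sub-interval length as a
#'   fraction of the site length.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L, n_tumours = 200L, n_normals = 50L,
                          tumour_types = "TYPE_A",
                          deletion_prevalence = 0.3,
                          effect_sizes = NULL,
                          default_z_shift = 1.5,
                          purity_shape = c(5, 2),
                          expression_noise_sd = 1,
                          baseline_log_fpkm = 3,
                          deleted_seg_mean_range = c(-1.0, -0.3),
                          neutral_seg_mean_sd = 0.03,
                          deletion_span_frac = c(0.4, 1)) {
  problems <- character()
  if (any(deletion_prevalence < 0 | deletion_prevalence > 1)) {
    problems <- c(problems, "deletion_prevalence must lie in [0, 1]")
  }
  if (n_normals < 2) problems <- c(problems, "n_normals must be >= 2")
  if (n_tumours < 1) problems <- c(problems, "n_tumours must be >= 1")
  if (expression_noise_sd <= 0) {
    problems <- c(problems, "expression_noise_sd must be > 0")
  }
  if (!is.null(purity_shape) &&
      (length(purity_shape) != 2 || any(purity_shape <= 0))) {
    problems <- c(problems, "purity_shape must be two positive Beta parameters or NULL")
  }
  if (length(deleted_seg_mean_range) != 2 ||
      any(deleted_seg_mean_range >= -0.1) ||
      deleted_seg_mean_range[1] > deleted_seg_mean_range[2]) {
    problems <- c(problems,
                  "deleted_seg_mean_range must be an interval entirely below -0.1")
  }
  if (length(deletion_span_frac) != 2 ||
      any(deletion_span_frac <= 0 | deletion_span_frac > 1) ||
      deletion_span_frac[1] > deletion_span_frac[2]) {
    problems <- c(problems, "deletion_span_frac must be an interval within (0, 1]")
  }
  if (!is.null(effect_sizes)) {
    stop_if_not_df(effect_sizes, "effect_sizes")
    require_columns(effect_sizes, c("gene_id", "site", "z_shift"),
                    "effect_sizes")
  }
  if (length(problems)) {
    abort(paste0("Invalid cohort configuration:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  structure(list(seed = as.integer(seed), n_tumours = as.integer(n_tumours),
                 n_normals = as.integer(n_normals),
                 tumour_types = tumour_types,
                 deletion_prevalence = deletion_prevalence,
                 effect_sizes = effect_sizes,
                 default_z_shift = default_z_shift,
                 purity_shape = purity_shape,
                 expression_noise_sd = expression_noise_sd,
                 baseline_log_fpkm = baseline_log_fpkm,
                 deleted_seg_mean_range = deleted_seg_mean_range,
                 neutral_seg_mean_sd = neutral_seg_mean_sd,
                 deletion_span_frac = deletion_span_frac),
            class = "cohort_config")
}

# Default planted effects: the first gene residing inside each site.
resolve_effect_sizes <- function(config, annotation) {
  if (!is.null(config$effect_sizes)) return(config$effect_sizes)
  sites <- annotation$sites
  genes <- annotation$genes
  eff <- purrr::pmap(sites, function(chrom, start, end, name, ...) {
    inside <- genes$chrom == chrom & genes$start >= start & genes$end <= end
    if (!any(inside)) return(NULL)
    tibble::tibble(gene_id = genes$name[which(inside)[1]], site = name,
                   z_shift = config$default_z_shift)
  })
  dplyr::bind_rows(eff)
}

#' Simulate a tumour cohort with planted fragile-site deletions
#'
#' Draws per-sample deletion status at each fragile site, places a deletion
#' segment (uniform `seg_mean` from the configured range) over a random
#' sub-interval of the site for deleted samples, adds near-zero background
#' segments everywhere, and generates expression on the log1p(FPKM) scale as
#' `baseline + z_shift * noise_sd * deleted * purity + noise` for tumours
#' and `baseline + noise` for normals (so a planted z-shift is exact on the
#' default analysis scale). All randomness is governed by `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param annotation Annotation list as from [demo_annotation()] (at least
#'   `sites` and `genes`; site must contain >= 1 gene for a planted effect).
#' @return List with `segments` (tibble, tumour samples only), `panel`
#'   (an [expression_panel()]), and `truth` (list of tibbles: `deletions`
#'   with per (sample, site) status and deleted sub-interval; `genes` with
#'   the planted direction per gene).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_tumours = 20, n_normals = 5),
#'                        demo_annotation(n_genes = 5))
#' sim$panel
#' @export
simulate_cohort <- function(config = cohort_config(),
                            annotation = demo_annotation()) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must come from cohort_config().")
  }
  sites <- annotation$sites
  genes <- annotation$genes
  validate_regions(sites, "annotation$sites")
  validate_regions(genes, "annotation$genes")
  effects <- resolve_effect_sizes(config, annotation)
  prev <- rep_len(config$deletion_prevalence, nrow(sites))
  withr::with_seed(config$seed, {
    tum_ids <- sprintf("T%04d", seq_len(config$n_tumours))
    norm_ids <- sprintf("N%04d", seq_len(config$n_normals))
    types_t <- rep_len(config$tumour_types, config$n_tumours)
    types_n <- rep_len(config$tumour_types, config$n_normals)
    purity <- if (is.null(config$purity_shape)) {
      rep(1, config$n_tumours)
    } else {
      rbeta(config$n_tumours, config$purity_shape[1], config$purity_shape[2])
    }

    # deletion status and deleted sub-interval per (tumour, site)
    del_rows <- purrr::imap(seq_len(nrow(sites)), function(si, ...) {
      st <- sites[si, ]
      deleted <- rbinom(config$n_tumours, 1, prev[si]) == 1
      span <- runif(config$n_tumours, config$deletion_span_frac[1],
                    config$deletion_span_frac[2]) * (st$end - st$start)
      del_start <- floor(st$start +
                           runif(config$n_tumours) * ((st$end - st$start) - span))
      del_end <- pmin(st$end, ceiling(del_start + pmax(span, 1)))
      tibble::tibble(sample_id = tum_ids, site = st$name, deleted = deleted,
                     del_start = ifelse(deleted, del_start, NA_real_),
                     del_end = ifelse(deleted, del_end, NA_real_))
    })
    del_truth <- dplyr::bind_rows(del_rows)

    # segments: background near-zero per chromosome + deletion segments
    chroms <- unique(c(sites$chrom, genes$chrom))
    extents <- purrr::map(chroms, function(ch) {
      s <- c(sites$start[sites$chrom == ch], genes$start[genes$chrom == ch])
      e <- c(sites$end[sites$chrom == ch], genes$end[genes$chrom == ch])
      tibble::tibble(chrom = ch, start = max(0, min(s) - 1e4),
                     end = max(e) + 1e4)
    }) |> dplyr::bind_rows()
    bg <- tidyr::expand_grid(sample_id = tum_ids, extents) |>
      dplyr::mutate(n_markers = as.integer((.data$end - .data$start) %/% 1e4),
                    seg_mean = rnorm(dplyr::n(), 0, config$neutral_seg_mean_sd))
    del_seg <- del_truth |>
      dplyr::filter(.data$deleted) |>
      dplyr::left_join(sites[, c("name", "chrom")],
                       by = c("site" = "name")) |>
      dplyr::transmute(sample_id = .data$sample_id, chrom = .data$chrom,
                       start = .data$del_start, end = .data$del_end,
                       n_markers = as.integer((.data$del_end - .data$del_start) %/% 1e3),
                       seg_mean = runif(dplyr::n(),
                                        config$deleted_seg_mean_range[1],
                                        config$deleted_seg_mean_range[2]))
    segments <- dplyr::bind_rows(bg, del_seg) |>
      dplyr::arrange(.data$sample_id, .data$chrom, .data$start)

    # expression on the log1p(FPKM) scale
    gene_ids <- genes$name
    n_genes <- length(gene_ids)
    baseline <- rep_len(config$baseline_log_fpkm, n_genes)
    all_ids <- c(tum_ids, norm_ids)
    x <- matrix(rnorm(n_genes * length(all_ids), 0,
                      config$expression_noise_sd),
                n_genes, length(all_ids),
                dimnames = list(gene_ids, all_ids))
    x <- x + baseline
    if (!is.null(effects) && nrow(effects)) {
      for (i in seq_len(nrow(effects))) {
        g <- effects$gene_id[i]
        del <- del_truth$deleted[del_truth$site == effects$site[i]]
        x[g, tum_ids] <- x[g, tum_ids] +
          effects$z_shift[i] * config$expression_noise_sd * del * purity
      }
    }
    fpkm <- expm1(pmax(x, 0))
    samples <- tibble::tibble(
      sample_id = all_ids,
      tumour_type = c(types_t, types_n),
      is_tumour = c(rep(TRUE, config$n_tumours), rep(FALSE, config$n_normals)),
      purity = c(purity, rep(NA_real_, config$n_normals)))
    panel <- expression_panel(fpkm, samples)

    gene_truth <- tibble::tibble(gene_id = gene_ids, direction = "none")
    if (!is.null(effects) && nrow(effects)) {
      idx <- match(effects$gene_id, gene_truth$gene_id)
      gene_truth$direction[idx] <- ifelse(effects$z_shift > 0, "up",
                                          ifelse(effects$z_shift < 0,
                                                 "down", "none"))
    }
    list(segments = segments, panel = panel,
         truth = list(deletions = del_truth, genes = gene_truth))
  })
}

#' Simulate an exon-level expression profile with a breakpoint
#'
#' Emulates the per-exon comparison between 3'-deleted and wild-type
#' patients: in "deleted" samples, exons inside the deleted central block
#' are shifted down by `shift` and the remaining exons up by `shift`;
#' wild-type samples are flat. Noise is Gaussian.
#'
#' @param n_exons Number of exons.
#' @param deleted_exons Integer indices of the deleted central block (must
#'   leave at least one exon outside).
#' @param n_deleted,n_wild_type Group sizes.
#' @param shift Planted shift (up outside the block, down inside).
#' @param noise_sd Gaussian noise SD.
#' @param seed Seed.
#' @return List with `values` (long tibble `exon_index`, `sample_id`,
#'   `value`), `labels` (tibble `sample_id`, `group`), `truth` (tibble
#'   `exon_index`, `direction`).
#' @export
simulate_exon_profile <- function(n_exons = 11, deleted_exons = 6:8,
                                  n_deleted = 20, n_wild_type = 20,
                                  shift = 1, noise_sd = 0.5, seed = 1L) {
  deleted_exons <- as.integer(deleted_exons)
  if (any(deleted_exons < 1 | deleted_exons > n_exons)) {
    abort("`deleted_exons` indices out of range.")
  }
  if (length(unique(deleted_exons)) >= n_exons) {
    abort("The deleted block must leave at least one exon intact.")
  }
  inside <- seq_len(n_exons) %in% deleted_exons
  withr::with_seed(seed, {
    ids_d <- sprintf("DEL%03d", seq_len(n_deleted))
    ids_w <- sprintf("WT%03d", seq_len(n_wild_type))
    mean_d <- ifelse(inside, -shift, shift)
    vals_d <- matrix(rnorm(n_exons * n_deleted, mean_d, noise_sd),
                     n_exons, n_deleted)
    vals_w <- matrix(rnorm(n_exons * n_wild_type, 0, noise_sd),
                     n_exons, n_wild_type)
    values <- tibble::tibble(
      exon_index = rep(seq_len(n_exons), times = n_deleted + n_wild_type),
      sample_id = rep(c(ids_d, ids_w), each = n_exons),
      value = c(as.vector(vals_d), as.vector(vals_w)))
    labels <- tibble::tibble(
      sample_id = c(ids_d, ids_w),
      group = rep(c("three_prime_deleted", "wild_type"),
                  c(n_deleted, n_wild_type)))
    direction <- if (shift == 0) {
      rep("none", n_exons)
    } else {
      ifelse(inside, if (shift > 0) "down" else "up",
             if (shift > 0) "up" else "down")
    }
    truth <- tibble::tibble(exon_index = seq_len(n_exons),
                            direction = direction)
    list(values = values, labels = labels, truth = truth)
  })
}

#' Simulate coverage tracks with a post-element signal drop
#'
#' Poisson per-base coverage over the span of a gene's exons, with mean
#' `mu` upstream of the element and `mu * drop_factor` from the element
#' start onward — the signature of an antisense element attenuating
#' transcription of its host gene.
#'
#' @param exons Region tibble of the gene's exons.
#' @param element One-row region tibble lying between two exons (no exon
#'   overlap).
#' @param drop_factor Downstream/upstream mean ratio in `[0, 1]`.
#' @param n_tracks Number of tracks (samples).
#' @param mu Upstream Poisson mean per base.
#' @param seed Seed.
#' @return List of [coverage_track()] objects.
#' @export
simulate_coverage <- function(exons, element, drop_factor = 0.3,
                              n_tracks = 14, mu = 100, seed = 1L) {
  validate_regions(exons, "exons")
  if (drop_factor < 0 || drop_factor > 1) {
    abort("`drop_factor` must lie in [0, 1].")
  }
  el_start <- element$start[[1]]
  el_end <- element$end[[1]]
  if (any(interval_overlap_bp(exons$start, exons$end, el_start, el_end) > 0) ||
      el_start < min(exons$end) || el_end > max(exons$start)) {
    abort("`element` must lie between two exons of the gene.")
  }
  span_start <- min(exons$start)
  span_end <- max(exons$end)
  pos <- span_start:(span_end - 1)
  lambda <- ifelse(pos < el_start, mu, mu * drop_factor)
  chrom <- exons$chrom[1]
  withr::with_seed(seed, {
    purrr::map(seq_len(n_tracks), function(i) {
      coverage_track(sprintf("TRACK%02d", i), chrom, span_start, span_end,
                     rpois(length(lambda), lambda))
    })
  })
}
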