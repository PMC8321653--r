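# fragilexpress

Tools for asking a specific cancer-genomics question: **when a focal
copy-number deletion hits a common fragile site (CFS), what happens to the
expression of the genes inside it?** Recurrent CFS deletions are usually
read as tumour-suppressor losses, but a deletion that removes an
*intragenic regulatory element* — for example an antisense pseudogene in an
intron of its host gene — can instead switch the surrounding gene **on**.
fragilexpress packages the full computational chain needed to detect such
events and their downstream correlates, driven end-to-end by a synthetic
cohort generator so that every stage is testable offline.

## What it computes

Given copy-number segmentation (SEG), an FPKM expression matrix with
sample metadata, and region annotation (BED):

1. **Deletion calls** — segments with log2 ratio strictly below −0.1
   qualify; a patient is deleted over a region on ≥ 1 bp overlap, with the
   bp-weighted mean segmentation value carried alongside.
2. **Z-scores vs normal tissue** — per tumour type and gene,
   `z = (x − μ_normal) / σ_normal` (SD with denominator n−1), on
   `log(1 + FPKM)` by default.
3. **Robust association** — per gene and fragile site,
   `z ~ deleted + purity` fitted by IRLS with Tukey's biweight
   (c = 4.685, MAD scale, Huber standard errors, t reference), Bonferroni
   correction over the fitted family, restriction to protein-coding genes
   with adjusted p < 0.01, direction from the sign of the deletion
   coefficient.
4. **Exon contrast** — per-exon mean difference between 3′-deleted and
   wild-type patients with a bootstrap confidence band.
5. **Instability signatures** — CIN25/CIN70 scores (mean signature-gene
   z), groups stratified by the deletion status of a chosen element,
   compared with the Mann-Whitney U test (exact below group size 8,
   tie-corrected normal approximation above).
6. **Nascent-transcription profile** — per-exon length-normalised
   coverage, `log(1 + ΣᵢEᵢ)` summed over samples, rescaled to [0, 1], plus
   a signed post-element drop statistic.

## Worked example

Generate a demo cohort (200 tumours, 50 normals, one fragile site whose
resident gene `G001` is planted with a +1.5 z-shift in deleted samples,
deletion prevalence 0.3, purity-diluted effects) and run the whole
pipeline from its YAML config:

```r
library(fragilexpress)
fx  <- make_fixtures(file.path(tempdir(), "demo"), seed = 1)
res <- run_pipeline(fx$config)

dplyr::select(res$significant, gene_id, region_name, beta_deletion,
              p_adjusted, direction, n_deleted, n_wild_type)
#> # A tibble: 1 × 7
#>   gene_id region_name beta_deletion p_adjusted direction n_deleted n_wild_type
#>   <chr>   <chr>               <dbl>      <dbl> <chr>         <int>       <int>
#> 1 G001    FS_A                 1.30   8.27e-12 up               62         138
```

The planted gene — and only it — comes back significantly **up**-regulated
in deleted patients: the coefficient 1.30 is the purity-diluted z-shift
(62 of 200 tumours are deleted), and 8.3 × 10⁻¹² is the Bonferroni-adjusted
p-value over the 20 fitted tests.

```r
res$cin_test
#> # A tibble: 1 × 5
#>   statistic p_value method    n1    n2
#>       <dbl>   <dbl> <chr>  <int> <int>
#> 1      4614   0.270 normal    60   140
```

The CIN25 comparison between element-deleted and intact patients is null
(p = 0.27) — as it should be here, since the demo cohort plants no
signature shift; the stage exists so a real shift can be measured the same
way.

```r
res$ttseq_drop
#> [1] -0.9966
```

The nascent-transcription profile collapses after the intragenic element
(the simulated tracks drop to 30% of the upstream mean after the element,
between exons 8 and 9): the mean rescaled expression of downstream exons
is ~1.0 lower than upstream. `plot_exon_contrast(res$exon_contrast)`,
`plot_signature_scores()` and `plot_exon_profile()` draw the three result
types.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/fragilexpress.R simulate --out demo --seed 1
Rscript inst/cli/fragilexpress.R run --config demo/config.yaml --verbose
```

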