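---
title: "Relating focal deletions at common fragile sites to gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating focal deletions at common fragile sites to gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragilexpress)
```

## The problem

Common fragile sites (CFS) are chromosomal regions prone to breakage under
replicative stress and are recurrently hit by focal deletions in tumours.
Most of these deletions do not obviously inactivate a tumour suppressor, and
some do the opposite: by removing an intragenic regulatory element — such as
an antisense pseudogene sitting in an intron of its host gene — a deletion
can *increase* the expression of the gene that surrounds it. fragilexpress
implements the computational side of that analysis as a reusable, tested
pipeline:

1. call per-patient deletions over named regions from copy-number
   segmentation;
2. z-score tumour expression against normal tissue of the same tumour type;
3. test the association between deletion status and expression with a
   robust linear model that includes tumour purity as a covariate, then
   Bonferroni-correct and keep significant protein-coding genes;
4. compare per-exon expression between patients deleted in the 3' portion
   of a gene and wild-type patients;
5. score chromosomal-instability expression signatures (CIN25/CIN70) and
   compare deletion-stratified groups with the Mann-Whitney U test;
6. compute an exon-level nascent-transcription profile from coverage
   tracks, revealing a signal drop downstream of an intragenic element.

Everything runs on synthetic cohorts generated by the package itself, so
every stage is testable without any external download.

## The model, stage by stage

### Deletion calling

Copy-number input is a segmentation table (SEG): per sample, genomic
intervals with a log2 copy-ratio (`seg_mean`). Segments qualify as deletion
evidence when `seg_mean < -0.1`; the inequality is strict, so a segment at
exactly −0.1 is excluded. For each (sample, region) pair, the sample is
called deleted when at least one qualifying segment overlaps the region by
one base or more. Alongside the binary call we keep `overlap_bp` (bases of
the region covered by the union of qualifying segments) and the
bp-weighted mean segmentation value
$\bar{s} = \sum_i o_i s_i / \sum_i o_i$, the patient-wise segmentation
value over the region. The binary ≥1 bp rule is the minimal reading of the
procedure; a minimum overlap or marker count is deliberately not imposed,
but both quantities are reported so a user can filter post hoc.

All coordinates inside the package are 0-based half-open. SEG input is
treated as 1-based inclusive (the TCGA convention) and converted once at
the reader boundary; BED and bedGraph are natively 0-based half-open and
pass through unchanged. Chromosome names are normalised to the `chrN` form
at read time. Fixing one internal convention, applied exactly once per
reader, is the cheapest way to kill off-by-one bugs in overlap arithmetic;
the overlap engine is a ~15-line sorted-merge union that the test suite
checks against a per-base brute-force oracle on a thousand random
instances.

### Z-scores against normal tissue

For each tumour type separately, each gene's reference mean $\mu_g$ and
standard deviation $\sigma_g$ (denominator $n-1$) are estimated from the
normal-tissue samples of that type, and each tumour sample is expressed as
$z_{gs} = (x_{gs} - \mu_g)/\sigma_g$. At least two normals are required;
genes with $\sigma_g = 0$ are dropped and reported. By default expression
is transformed as $\log(1 + \mathrm{FPKM})$ before z-scoring
(`log_transform = TRUE`): FPKM is heavy-tailed and z-scores on the raw
scale are dominated by the very outliers the robust model would then have
to absorb. The switch is exposed because the choice of scale is a genuine
analysis decision, not a mathematical necessity.

### Robust association with purity covariate

For each gene and region the package fits

$$z_{g} \sim \beta_0 + \beta_{\mathrm{del}}\,\mathbb{1}[\text{deleted}] +
\beta_{\mathrm{pur}}\,\text{purity}$$

by iteratively reweighted least squares with Tukey's biweight
$\psi$-function, which gives gross outliers exactly zero weight. Tumour
purity matters because bulk expression is a mixture: in an impure sample a
tumour-cell-autonomous effect is diluted toward the normal-cell signal, so
purity is a genuine confounder of the deletion–expression relationship.

Numerical choices, pinned for reproducibility:

* tuning constant $c = 4.685$ (95% efficiency at the Gaussian model);
* residual scale re-estimated at every iteration as
  $\mathrm{median}(|r|)/0.6745$ (MAD about zero);
* convergence when the largest relative coefficient change falls below
  $10^{-8}$, cap of 50 iterations;
* standard errors by Huber's asymptotic formula with the small-sample
  correction factor, two-sided p-values from the $t$ distribution with
  residual degrees of freedom.

On outlier-free data the biweight fit coincides with ordinary least
squares; the residual gap between the two estimators is proportional to
the noise SD (it is a fixed fraction of the sampling error), which is why
the numerical-agreement test uses a low-noise fixture (SD 0.01, where
agreement to $10^{-3}$ is the correct statement of "biweight ≈ OLS") and
the outlier-resistance test uses unit noise. Samples with missing purity
are dropped from the fit, with a per-row count in the output — imputation
would manufacture information the data do not contain. Fits with fewer
than `min_group = 3` samples in either deletion group, or a rank-deficient
design (e.g. every sample deleted), are flagged `untestable` and carry no
p-value.

P-values are Bonferroni-corrected with family size $m$ = the number of
tests actually fitted in the run, the most conservative defensible family,
and reported explicitly (attribute `"m"` and the run log). Genes are kept
when protein-coding and adjusted p < 0.01; direction is the sign of
$\beta_{\mathrm{del}}$.

### Exon contrast

The per-exon comparison between 3'-deleted and wild-type patients is the
difference of group means per exon with a percentile bootstrap band
(resampling samples within each group, seeded, B configurable). Deletion
patterns are classified from calls over the 5'/central/3' portions of the
gene with the pinned precedence 3' > central, so a deletion spanning both
lands deterministically in the 3'-deleted group. Sub-gene portions are
user-supplied intervals: where a gene's "3' portion" begins is an
annotation decision, not something the package should guess.

### Instability signatures

A sample's signature score is the mean z-score of the signature genes
found in the panel — the minimal monotone aggregate consistent with
"higher score = higher instability"; missing genes are reported, never
imputed, and the aggregation is recorded in the output metadata. The
shipped CIN25/CIN70 lists are transcriptions from the
chromosomal-instability signature literature (their file names and headers
say so) and any list can be substituted via `read_signature()`; no
computation depends on the symbol content. Groups are compared with the
Mann-Whitney U test: the reported U is that of the first-listed group
(element-deleted), and the two-sided p-value is computed by exact
enumeration of rank assignments when both groups have ≤ 7 samples
(midranks handle ties), and by the tie-corrected normal approximation
without continuity correction above that. The exact path is implemented in
the package because the stock test switches to an approximation whenever
ties appear; the tests cross-check both paths against `wilcox.test` and a
combinatorial oracle.

### Nascent-transcription exon profile

From per-base coverage tracks (bedGraph; the text equivalent of bigwig)
the package computes, per exon $e$ and track $i$, the length-normalised
signal $E_{e,i}$, then the exon expression
$\log\!\left(1 + \sum_i E_{e,i}\right)$ (natural log, summing across
samples before the log, exactly as the formula reads), and rescales the
resulting vector to $[0, 1]$. Exon ordinals follow transcription
direction, so minus-strand genes have their coordinate-sorted exon list
reversed. The post-element drop statistic is the mean rescaled expression
of exons downstream of the element minus the mean upstream; negative
values indicate attenuation after the element. Rescaling makes the log
base irrelevant for ordering but not for intermediate values, which is why
the base is pinned (natural log) and recorded. A constant expression
vector rescales to all zeros with a warning rather than 0/0.

## The synthetic cohort generator

`simulate_cohort()` draws, per tumour sample and fragile site, a deletion
indicator at the configured prevalence and, for deleted samples, a
deletion segment with `seg_mean` uniform in [−1.0, −0.3] — safely below
the −0.1 filter while exercising value variation — over a random
sub-interval of the site. Background segments everywhere have
`seg_mean` ~ N(0, 0.03). Expression is simulated directly on the
$\log(1+\mathrm{FPKM})$ scale as

$$x_{gs} = \text{baseline}_g + \Delta_g\,\sigma\,\mathbb{1}[\text{deleted}_s]\,\text{purity}_s + \varepsilon_{gs},
\qquad \varepsilon \sim N(0, \sigma^2),$$

then mapped to FPKM by $\exp(x) - 1$ (clamped at zero; with the default
baseline of 3 the clamp probability is ~$10^{-3}$ per value). Simulating on
the analysis scale makes the planted effect $\Delta$ an *exact* z-shift
under the default transform, so recovery tests have a closed-form target.
Purity multiplies the planted effect, not the baseline: that is the
minimal model in which purity genuinely confounds the deletion–expression
relationship and the regression covariate has something to absorb.
Normals are baseline plus noise.

Default study conditions: 200 tumours, 50 normals, one tumour type,
deletion prevalence 0.3, one resident gene planted with z-shift +1.5,
purity ~ Beta(5, 2) (mean ≈ 0.71, typical of bulk purity estimates), unit
noise. Where no value was externally fixed (purity law, baseline, noise),
the defaults were chosen once as field-plausible and are not tuned; the
planted effect size is chosen for test power, not biological realism.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: no realistic CNV breakpoint process, no
inter-gene correlation beyond the planted signature block, no read-level
sampling noise, no batch effects, no multiple overlapping fragile sites
per chromosome. The generator establishes that the statistics do what they
claim under their own assumptions, not that those assumptions hold in any
particular cohort.

`simulate_exon_profile()` plants a breakpoint pattern (up-shift outside a
deleted central exon block, down-shift inside) on otherwise flat profiles;
`simulate_coverage()` draws per-base Poisson coverage with mean $\mu$
upstream of an intragenic element and $\mu \times \text{drop\_factor}$
from the element start onward (the within-element convention is inert for
the drop statistic, which only uses exons strictly before and after the
element).

## Reproducibility and problem sizes

Every stochastic function takes a seed and restores the RNG state on exit
(`withr::with_seed`), so identical seed + config gives bit-identical
output; the pipeline writes a provenance JSON (config, package version,
seed) sufficient to re-run any result. The test-suite and acceptance
simulations use cohorts of 200 tumours / 50 normals with up to 500 genes,
20–50 replicate seeds per statistical claim, and 50-base–resolution
coverage windows of ~36 kb — sizes chosen so each claim is tested with
enough replicates for its binomial tolerance while the whole suite stays
interactive.

## Known limitations

* The Bonferroni family is defined per run; merging runs requires
  re-correcting with the pooled family size.
* Purity enters linearly; a mixture-model deconvolution is out of scope.
* The exact Mann-Whitney path enumerates $\binom{n_1+n_2}{n_1}$
  assignments and is restricted to groups of ≤ 7 for that reason.
* The bedGraph reader loads a dense per-base window; megabase windows are
  memory-hungry. A bigwig-backed reader could wrap the same contract.
* `classify_gene_deletion()` trusts the user-supplied portion boundaries;
  it checks disjointness, not biological sense.

## A worked demonstration

```{r demo, eval = FALSE}
fx <- make_fixtures(file.path(tempdir(), "demo"), seed = 7)
res <- run_pipeline(fx$config, verbose = TRUE)
res$significant    # the planted gene, direction "up"
res$cin_test       # Mann-Whitney U and p for CIN25 by element deletion
res$ttseq_drop     # negative: transcription drops after the element
plot_exon_contrast(res$exon_contrast)
```
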