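Package: fragilexpress
Title: Deletion-Expression Analysis at Common Fragile Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate focal copy-number deletions at common fragile
    sites to the expression of the genes that reside in them. Reads
    copy-number segmentation (SEG), region annotation (BED), FPKM expression
    matrices and bedGraph coverage; calls per-patient deletions from filtered
    segments; z-scores tumour expression against normal tissue per tumour
    type; tests deletion-expression association with a Tukey-biweight robust
    linear model including tumour purity as a covariate, with Bonferroni
    correction; scores chromosomal-instability expression signatures (CIN25,
    CIN70) and compares deletion-stratified groups with the Mann-Whitney U
    test; and computes exon-level nascent-transcription profiles
    (length-normalised coverage, log(1 + sum) transform, unit rescaling). A
    seeded synthetic-cohort generator with planted deletions, cis expression
    effects and purity dilution makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
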