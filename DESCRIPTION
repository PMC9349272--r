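Package: stratmeth
Title: PRS-Stratified Epigenome-Wide Association and Poly-Methylomic Profile Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for epigenome-wide association analyses in
    cohorts stratified by polygenic risk. Covers clumping-and-thresholding
    polygenic scoring from GWAS summary statistics with Nagelkerke pseudo-R2
    threshold optimisation, genotype relatedness and ancestry handling,
    CpG probe filtering (data variability, blood-variable and blood-brain
    concordance lists, probe-SNP exclusion), reference-based blood cell-type
    deconvolution, surrogate-variable estimation, per-probe linear models on
    M-values with empirical-null bias and inflation correction via a Gibbs
    sampler, quintile stratification, poly-methylomic profile scores with
    validation general linear models, and regulatory-domain gene mapping with
    hypergeometric gene-set enrichment. Includes a synthetic-cohort generator
    with known ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    limma,
    car,
    quadprog,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    optparse
Config/testthat/edition: 3
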