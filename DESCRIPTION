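Package: meQTLmediate
Title: Methylation QTL Mapping and Causal Mediation Analysis in Lymphocytes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis linking disease-risk genetic variants to
    DNA methylation (meQTLs) and onward to gene expression (eQTMs) in
    isolated immune-cell subsets. Provides additive linear meQTL and
    Genotype x Diagnosis interaction scans with Benjamini-Hochberg FDR,
    greedy LD clumping and proxy lookup, GWAS risk-locus intersection with
    Bayesian colocalization via Wakefield approximate Bayes factors,
    windowed Spearman eQTM mapping, a four-component causal inference test
    (CIT) with permutation-based FDR for SNP-CpG-transcript triplets,
    chromatin-state and TFBS enrichment, a Storey-type cross-cell-type
    sharing estimator, allelic expression imbalance testing, and a
    synthetic-cohort generator with planted causal structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    IRanges,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
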