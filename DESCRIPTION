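Package: txvar
Title: Cross-Study Ranking and Analysis of Gene Expression Variance
Version: 0.1.0
Authors@R:
    person("txvar", "developers", email = "txvar@example.org", role = c("aut", "cre"))
Description: Tools for studying the landscape of transcriptional variance
    across bulk RNA-seq studies. Provides a per-study processing pipeline
    (count filtering, variance stabilizing transformation, fixed-effect
    covariate correction, robust-PCA outlier removal, residual standard
    deviations), construction of the gene-by-study SD matrix and the
    study-by-study Spearman correlation matrix with principal coordinate
    embedding, a Bayesian dyadic random-effects model for Fisher
    z-transformed study-pair correlations, PC1-projection consensus
    variance and mean ranks with PCA-based imputation of missing entries,
    decile-based functional statistics (Shannon entropy and skewness of
    gene-set decile profiles, hypergeometric enrichment, environmental
    responsiveness tests), gene-level covariates of the rank (co-expression
    connectivity, genomic window metrics, chromatin-state proportions,
    partial Spearman correlations), and a synthetic multi-study data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
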