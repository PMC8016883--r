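Package: logoscan
Title: Scan Statistics for Local Genetic Correlation from GWAS Summary Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies small genome segments harboring local genetic
    correlation between two complex traits using only GWAS summary
    statistics and a reference genotype panel. A scan statistic --
    an LD-score-penalized inner product of two z-score vectors --
    is maximized over variable-size windows within approximately
    LD-independent blocks, and assessed against a Monte-Carlo null
    obtained by block-tridiagonal conditional Gaussian sampling of
    pseudo z-scores. Includes minimal LD-score-regression estimators
    (heritability, cross-trait genetic covariance with a sample-overlap
    intercept, stratified covariance), liability/observed scale
    conversion, adaptive tuning-parameter selection, genotype and
    phenotype simulators for power and calibration studies, detection
    metrics, and an annotation-enrichment permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    matrixStats,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
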