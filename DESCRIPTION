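Package: indicusGP
Title: Genomic Prediction Pipeline for Bos indicus Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end genomic prediction for beef cattle populations
    genotyped with dense SNP panels: iterative genotype quality control,
    pedigree (A), genomic (G) and blended (G*) relationship matrices,
    deregression of estimated breeding values into weighted
    pseudo-phenotypes, whole-genome regression by GBLUP (with optional
    residual polygenic blending), BayesC and Bayesian LASSO Gibbs
    samplers, forward and cross-validation designs (random and k-means
    genomic clustering), relatedness-versus-accuracy diagnostics, and
    expected-accuracy theory based on effective chromosome segments.
    Includes a pedigree/LD-aware synthetic population simulator so the
    whole pipeline can be exercised without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Rcpp,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
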