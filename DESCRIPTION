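Package: metaboqtl
Title: Metabolite QTL Mapping, Heritability and Metabolic Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for genetic analysis of targeted metabolomics data in
    pedigreed livestock cohorts. Implements metabolite quality control and
    Box-Cox normalization with covariate residualization, pedigree and genomic
    relationship matrices with REML heritability estimation, linear mixed model
    genome-wide association for single metabolites and metabolite ratios (with
    the p-gain statistic), sample-size-weighted Z-score meta-analysis, mQTL
    region calling and gene annotation, Gaussian graphical model reconstruction
    of metabolite networks from full-order partial correlations, and a
    first-order kinetic model of the kynurenine pathway. Includes a synthetic
    cohort generator (pedigree, LD-structured genotypes, planted mQTL) for
    power studies and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    deSolve,
    generics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
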