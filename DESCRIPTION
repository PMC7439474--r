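Package: scfaferm
Title: In Vitro SCFA Fermentation Analysis and Multinomial Logistic-Normal
    Regression for Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing in vitro fecal fermentation experiments that
    screen prebiotic substrates for short-chain fatty acid (SCFA) production.
    Implements gas-chromatography standard-curve calibration, control-corrected
    total-SCFA fold changes, two-way ANOVA and nonparametric screening
    statistics, genus amalgamation and prevalence filtering of 16S count
    tables, log-ratio coordinate transforms, and a Bayesian multinomial
    logistic-normal linear regression (pibble-type model) with matrix-normal /
    inverse-Wishart priors, fitted by marginal (matrix-T) Laplace
    approximation with conjugate uncollapsing, for associating taxon
    composition with SCFA production. A synthetic-data generator emulates the
    fermentation study design (donors x prebiotics with duplicate vessels and
    genus-level count tables) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    vegan,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'scfaferm-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'counts.R'
    'scfa.R'
    'io.R'
    'logratio.R'
    'pibble.R'
    'pibble-summary.R'
    'stats.R'
    'pipeline.R'
    'synthetic.R'
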