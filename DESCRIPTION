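Package: liabped
Title: Heritability of Binary Threshold Traits on Pedigrees
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-genetic analysis of binary (threshold) traits
    recorded on pedigreed populations, built around the dog eye-screening
    setting: validation and topological ordering of pedigrees, inbreeding
    coefficients and the additive relationship matrix with its sparse
    inverse, cleaning of repeated clinical examinations under the "once
    affected = affected" rule, prevalence and screening-coverage
    descriptives, linear animal-model variance components by average
    information REML on the observed 0/1 scale, a Bayesian threshold
    (liability) animal model fitted by Gibbs sampling with the residual
    variance restricted to unity and the genetic variance sampled from the
    parental subset, effective sample size and highest posterior density
    diagnostics, the Dempster-Lerner conversion of observed-scale
    heritability to the liability scale, breeding-value comparison across
    model families, and a litter-structured pedigree and examination-record
    simulator for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
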