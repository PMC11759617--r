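Package: pcmatch
Title: Projected Principal-Component Matching for Cross-Cohort Case-Control GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects biobank participants genetically matched to a smaller
    disease cohort via principal components projected from a reference PCA,
    using propensity-score subclassification, then runs quality-controlled
    case-control logistic association with Firth fallback, inverse-variance
    fixed-effect meta-analysis with harmonization filters and LD clumping,
    genomic-control diagnostics, and analytic power calculations for additive
    disease models. Includes a simulator for admixed two-cohort case-control
    data (Balding-Nichols differentiated allele frequencies, Dirichlet
    admixture, liability phenotypes with ancestry confounding and noisy
    proxy case status) used to exercise and calibrate the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
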