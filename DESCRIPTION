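Package: methylpace
Title: Longitudinal Methylation Dynamics and Multi-Organ Pace of Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal epigenome-wide analyses of DNA
    methylation in ageing cohorts. Classifies CpG sites as age-associated
    (mean methylation shifts with age) or age-varying (between-individual
    heterogeneity in methylation trajectories) by comparing nested
    random-intercept and random-slope linear mixed models fitted by
    maximum likelihood, extracts per-subject methylation change rates as
    random-slope BLUPs, derives phenotype-specific and organ-system
    composite pace-of-aging scores, links methylation change rates to
    organ paces by covariate-adjusted Pearson partial correlation, and
    provides Fisher-exact set enrichment, hypergeometric
    over-representation analysis, and semantic-similarity based
    redundancy reduction of enriched terms. Ships a synthetic
    longitudinal cohort generator with ground-truth tables for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
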