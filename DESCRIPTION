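Package: groupfdr
Title: Gene-Level False Discovery Rate Control for Grouped eQTL Tests
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Empirical-Bayes random-effects modelling for gene-level false
    discovery rate control in cis-eQTL studies. Each gene forms a group of
    SNP-level association tests; a two-group mixture with a Fisher-scale
    random effect for the causal-SNP correlation yields gene-level local
    false discovery rates, which are thresholded adaptively to control the
    FDR. Provides a fast summary-statistic fit from z-statistics alone
    (pseudo-likelihood), a full-data fit via an EM algorithm with
    Gauss-Hermite quadrature, baseline gene-level procedures (Bonferroni,
    Simes, permutation min-p with Storey q-values), simulation engines for
    serially correlated z-statistics and genotype-conditioned expression,
    and replicate evaluation of realized FDR and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
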