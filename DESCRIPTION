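Package: otubench
Title: Benchmarking Multivariate ANOVA-Like Methods for Microbiome
    Intervention Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compositional preprocessing (filtering, multiplicative zero
    replacement, centred log-ratio transformation), community-level tests
    (ASCA, 50-50 MANOVA, PERMANOVA, ANOSIM), OTU-level differential-abundance
    procedures (SIMPER, rotation-test adjusted p-values, PLS-DA/VIP with
    uninformative-variable elimination, ANCOM W, a Dirichlet Monte-Carlo clr
    test, a negative-binomial GLM Wald test), a Gamma/multivariate-
    hypergeometric count simulator with configurable fold-change scenarios,
    and a TPR/TNR/rank-agreement evaluation harness for comparing the
    methods on simulated dietary-intervention designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    DESeq2,
    mixOmics,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
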