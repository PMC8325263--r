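Package: ttcqtl
Title: Heterotic QTL Mapping and Genomic Prediction in Triple Testcross Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of triple testcross (TTC) experiments for
    dissecting heterosis. Simulates recombinant-inbred-line base populations and
    their testcross progenies with configurable additive, dominance and digenic
    epistatic QTL architectures; computes best linear unbiased estimates across
    blocks, mid-parent heterosis and the Z1/Z2/Z3 linear transformations of
    testcross family means; maps augmented additive, augmented dominance and
    epistatic heterotic QTLs by one- and two-dimensional genome scans with
    stepwise background-marker control and permutation thresholds; and performs
    GBLUP genomic prediction under the general/specific combining ability model
    with REML variance components, heritability estimation, cross-validation and
    marker-subset experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
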