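Package: serialabc
Title: Temporal-Sample Approximate Bayesian Computation for Effective
    Population Size Change in Insect Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies changes in effective population size
    (Ne) from temporally spaced microsatellite samples, as arise when
    vector-control interventions (indoor residual spraying, insecticidal
    nets) suppress mosquito populations.  Provides a serial-coalescent
    simulator with a generalized stepwise mutation model for
    microsatellites, the standard within- and between-sample summary
    statistics (unbiased expected heterozygosity, rarefied allelic
    richness, effective allele number, allele-size variance, M ratio,
    Weir-Cockerham theta), rejection Approximate Bayesian Computation with
    logistic-regression model choice among competing demographic scenarios
    (constant, increasing, bottleneck, fluctuating), local-linear
    regression parameter adjustment, confidence estimation for scenario
    choice via pseudo-observed datasets, GenePop input/output, and a
    synthetic study generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
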