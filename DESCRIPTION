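Package: ncatools
Title: Network Component Analysis of Transcription-Factor Regulatory Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative dissection of transcription-factor gene-regulatory
    networks by network component analysis (NCA). Given a signed ternary
    TF-to-gene connectivity pattern and condition-wise expression ratios,
    ncatools tests structural identifiability (NCA compliance), prunes
    non-identifiable networks to compliant subnetworks, decomposes log10
    expression into connectivity strengths and log TF activities by
    alternating least squares under the fixed zero pattern, normalizes the
    per-TF scaling gauge, corrects sign indeterminacies against documented
    regulatory directions, aggregates across biological replicates and
    random restarts, and evaluates the fit (reconstruction R-squared,
    TF-activity versus TF-mRNA parity, pairwise condition tests). A
    synthetic-data generator produces compliant ground-truth networks and
    noisy replicate expression so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
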