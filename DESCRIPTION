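Package: topotestr
Title: Topology Hypothesis Testing, Bayes Factors and Bait Design for
    Target-Capture Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discriminating between competing
    phylogenetic tree topologies from target-capture supermatrices.
    Provides fixed-topology likelihood evaluation under empirical
    amino-acid substitution models with discrete-gamma rate
    heterogeneity (Felsenstein pruning with branch-length
    optimisation), site-likelihood-based hypothesis tests (likelihood
    ratios, RELL bootstrap, the approximately unbiased test, BIC
    posterior probabilities), marginal-likelihood estimation from MCMC
    log-likelihood traces via a moving harmonic-mean estimator with
    Bayes-factor evidence classification, supermatrix concatenation
    and occupancy statistics, and a hybridization-capture bait-design
    filter (tiling, N-run cleaning, hit and melting-temperature
    specificity rules). A synthetic-data module simulates alignments,
    missingness patterns, autocorrelated posterior traces and
    site-likelihood matrices so every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
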