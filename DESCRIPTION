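Package: hbdkit
Title: Genome-Wide Homozygosity-by-Descent Estimation and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of individual genome-wide homozygosity-by-descent
    (autozygosity) from SNP genotypes, and tools to benchmark the estimators
    against known truth. Implements four single-point measures (multilocus
    heterozygosity, the PLINK-style moment estimator, an inverse-variance
    weighted locus-based estimator, and a single-point maximum-likelihood
    estimator) and a multi-point maximum-likelihood estimator based on a
    two-state hidden Markov model of autozygosity along the genetic map.
    Includes a gene-dropping simulator on explicit cousin pedigrees that
    yields genotypes with exactly known homozygosity-by-descent, marker
    quality-control filters with an exact Hardy-Weinberg test, greedy
    r-squared-threshold marker pruning, and a comparison pipeline producing
    per-estimator summaries, rank-correlation matrices and nonparametric
    group and sibling-pair tests. Reads and writes PLINK text PED/MAP files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
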