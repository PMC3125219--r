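Package: concertr
Title: Conversion-Aware Evolutionary Analysis of Duplicated Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the concerted evolution of tandemly
    duplicated gene families such as the vertebrate Toll-like receptor 1
    (TLR1) family. Detects gene-conversion tracts between paralogues with a
    Sawyer-style maximal-run statistic (permutation and exact run-length
    tail p-values) and sliding-window bootscan profiles; partitions codon
    alignments into converted and conversion-free regions; builds distance
    and maximum-likelihood phylogenies with bootstrap support and quartet
    likelihood mapping; dates duplication and conversion events under
    global and local molecular clocks with fossil calibrations; tests for
    positive selection with Goldman-Yang codon site-class mixtures (M0,
    M1a, M2a, M7, M8, M8a), likelihood-ratio tests and naive empirical
    Bayes site identification; scans protein alignments for correlated
    (co-evolving) amino-acid sites within and between interacting
    receptors; and discriminates gene conversion from convergent evolution
    by codon-usage concordance. A Gillespie codon-substitution simulator
    with interval gene conversion, omega site classes and coupled site
    pairs provides ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
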