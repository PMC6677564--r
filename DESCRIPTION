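Package: edgepop
Title: Microsatellite Diversity, Population Structure and Coalescent ABC for
    Range-Edge Endemics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic analysis toolkit for small panels of
    microsatellite (SSR) genotypes and plastid spacer alignments from few,
    small populations, as typical of narrowly endemic plants at the margin of
    their genus range. Provides per-locus diversity statistics (allele
    frequencies, gene diversity, PIC, rarefied allelic richness, null-allele
    estimators, exact Hardy-Weinberg tests, Weir-Cockerham F_IS), haplotype
    and nucleotide diversity for plastid alignments, AMOVA with permutation
    tests, pairwise F_ST and DAPC ordination, and a single-population
    coalescent simulator under the generalized stepwise mutation model driving
    approximate Bayesian computation (ABC) model choice among four demographic
    scenarios, with local-linear posterior parameter estimation, predictive
    error and posterior model checking. A synthetic-data generator emulating
    the study design of two range-edge Solanaceae makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    nnet,
    ape,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
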