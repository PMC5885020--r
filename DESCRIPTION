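Package: phagani
Title: ANI-Based Delineation and Recombination Analysis of Lytic Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates natural groups of lytic dsDNA bacteriophages from
    whole-genome sequences by fragment-based average nucleotide identity (ANIb)
    with alignment coverage, and characterizes gene flow within and between the
    resulting groups. Provides a seeded local aligner with an exact
    Smith-Waterman fallback, ortholog family clustering under an amino-acid
    identity and coverage rule with core-genome extraction, TN93 distances and
    neighbour-joining trees, the pairwise homoplasy index (PHI) recombination
    test with a permutation null, a SNP-density clonal-frame scan, congruence
    among gene distance matrices (CADM and Mantel tests), frequency-weighted
    consensus splits from gene trees, and a synthetic phage-genome evolution
    simulator with a recorded truth log so every stage can be validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    mclust,
    jsonlite,
    graphics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    vegan
Config/testthat/edition: 3
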