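Package: rnadesign
Title: RNA Inverse Folding by Multifrontier Ensemble Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Designs RNA sequences that fold into a given pseudoknot-free
    secondary structure by iteratively optimizing an ensemble objective
    (equilibrium probability of the target, or normalized ensemble defect)
    with a structure-aware stochastic local search.  The search keeps a
    frontier of the k best candidates seen so far, samples candidates and
    mutation positions from Boltzmann distributions, applies structured
    mutations over local motifs (stacks and loop mismatches), and harvests
    every intermediate sequence whose minimum free energy structure matches
    the target as a design byproduct.  Ships a self-contained nearest-pair
    energy model with exact dynamic programming (partition function,
    base-pair probabilities, MFE set) plus a brute-force enumeration oracle,
    and an adapter for the ViennaRNA command-line programs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
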