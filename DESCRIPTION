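Package: metacna
Title: Copy-Number Alterations in Mammalian Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds enzyme orthology networks from genome-scale metabolic
    models (SBML), collapses genes into isoenzyme groups, maps target
    genomes onto the network through orthology tables, reconstructs
    ancestral gene copy numbers on a fixed phylogeny by linear (Wagner)
    parsimony, calls per-branch copy-number alterations (CNAs), tests
    their clustering in the network by permutation, and associates
    branch-wise CNAs with phenotypic traits via correlation-based feature
    selection, least-median-of-squares regression, leave-one-species-out
    prediction and permutation significance with false-discovery-rate
    control. Includes a synthetic-data generator with full ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    igraph,
    ape,
    vegan,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
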