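Package: aflphylo
Title: AFLP Phylogenetics: Fragment-Sharing Distances, Parsimony,
    Resampling Tests and Ancestral-State Reconstruction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for phylogenetic analysis of binary AFLP
    (amplified fragment length polymorphism) presence/absence matrices:
    Nei-Li fragment-sharing distances and neighbor joining, Fitch
    parsimony scoring and constrained heuristic search, nonparametric
    bootstrap bipartition support, tree-length skewness (g1)
    randomization, Shimodaira-Hasegawa topology tests via RELL
    resampling, the homoplasy excess test for hybridization, and
    ancestral reconstruction of discrete traits by unordered parsimony
    (with polytomy-resolution enumeration and transition-count ranges)
    and by the one-parameter Markov (Mk1) model. Includes a calibrated
    synthetic AFLP generator with known ground truth, readers/writers
    for NEXUS, relaxed PHYLIP and CSV binary matrices, and a pipeline
    driver that produces a structured analysis report.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
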