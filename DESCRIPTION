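Package: gannet
Title: Gene Association Network Reconstruction from Perturbation Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs gene association networks from perturbation
    transcriptome experiments with a shrinkage partial-correlation Gaussian
    graphical model and empirical-null edge probabilities, evaluates the
    reconstructed networks against reference interactomes by
    topology-preserving node-label permutation tests (common edges and mean
    shortest path, with k-order reference expansion), and analyses the
    selected network by rank-consensus centrality, k-neighborhood extraction
    and Fisher over-representation. A synthetic-data module generates
    knockdown/overexpression perturbation studies from known sparse precision
    matrices so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
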