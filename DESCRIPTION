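Package: panforest
Title: Random-Forest Screening of Gene Co-Occurrence in Bacterial Pangenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decides which accessory genes in a bacterial pangenome are
    predictable from the other genes present. Gene presence-absence matrices
    (Roary/Panaroo dialects) are filtered, collapsed into unique
    presence-absence patterns (PAPs), and each PAP is predicted from all
    others with a Random Forest. Phylogenetic confounding is removed with the
    Fritz-Purvis D statistic and a Fitch parsimony threshold, a false-discovery
    rate is calibrated by simulating genes independently under a two-state
    all-rates-different Markov model on the tree, and surviving
    predictor-target links are classified as putative mutualism, commensalism,
    or competition. Includes a synthetic benchmark generator with planted
    gene-gene coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    ranger,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
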