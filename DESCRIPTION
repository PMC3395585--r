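Package: tadnet
Title: Tree-Average Distances on Rooted Phylogenetic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward and inverse modelling of the tree-average distance on
    rooted phylogenetic networks.  A weighted network with inheritance
    probabilities at each hybrid vertex induces an expected path distance
    over its displayed trees; for normal, semibinary networks these
    distances between base-set taxa determine every arc weight and every
    inheritance probability.  The package validates networks (tree-child,
    redundant-arc and semibinary checks), enumerates parent maps and
    displayed trees, computes tree-average distance matrices in exact
    rational arithmetic, and recovers weights and inheritance
    probabilities from exact distances by a closed-form case analysis.
    Includes extended-Newick and PHYLIP square-matrix input/output, a
    generator of random normal semibinary networks, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
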