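Package: rnacurve
Title: Dynamic 3D Graphical Representation and Alignment-Free Comparison of
    RNA Secondary Structures
Version: 1.0.0
Author: rnacurve developers
Maintainer: rnacurve developers <rnacurve@example.org>
Description: Encodes RNA secondary structures (dot-bracket with extended
    pseudoknot brackets, CT, or BPSEQ) as 8-letter characteristic sequences
    in which paired bases are marked, maps each characteristic sequence onto
    three dynamic 3D curves driven by the amino/keto, purine/pyrimidine and
    weak/strong chemical dichotomies, collapses the curves into a
    36-dimensional geometric-center descriptor, and measures structural
    dissimilarity between two RNAs as the quotient of the Euclidean distance
    between their descriptors and the cosine of the angle between them.
    Includes UPGMA clustering with Newick export and cluster-purity
    evaluation, a reproducible generator of random valid structures and
    family-structured synthetic datasets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
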