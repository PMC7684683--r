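Package: treelink
Title: Tree-Linked Assay Experiments with Node-Level Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A container for assay matrices whose rows and/or columns are
    linked to the nodes of rooted trees, as arises with OTU count tables
    linked to phylogenies or taxonomies and with cytometry cluster
    profiles linked to cluster dendrograms. The container extends
    SummarizedExperiment with row and column trees plus automatically
    maintained link tables, and supports tree-aware subsetting without
    pruning, tree replacement, leaf-subsetting with pruning and node
    tracking, and aggregation of assay data to arbitrary node sets with
    metadata collapse. Also provides a node-algebra toolkit for rooted
    labeled trees (descendants, ancestors, lowest common ancestors, leaf
    unions, node joining, path matrices, pruning, labeling), conversion
    of ordered-rank taxonomy tables into trees with detection and
    resolution of polyphyletic loops, delimited-text/Newick/FASTA bundle
    input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
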