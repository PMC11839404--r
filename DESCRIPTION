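Package: paleoplace
Title: Ancient DNA Damage Simulation and Phylogenetic Placement Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates post-mortem ancient DNA damage under the Briggs model
    (backbone nicks, geometric single-stranded overhangs, and context-dependent
    cytosine deamination) directly on aligned or unaligned FASTA sequences, and
    evaluates phylogenetic placement accuracy with topological node distance and
    expected node distance over jplace placements. Includes a pruning-based
    benchmark harness with a built-in distance placer, closed-form companions
    (theoretical median fragment length, expected misincorporation profiles,
    standardized linear models of placement error), and generators for synthetic
    sequences, trees, and tree-evolved alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
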