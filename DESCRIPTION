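Package: ffdcj
Title: Family-Free DCJ Distance and Similarity Between Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome comparison under the double-cut-and-join (DCJ)
    rearrangement model without prior gene family assignment. Implements
    the classical adjacency-graph DCJ distance for duplication-free
    genomes, the family-free DCJ distance and similarity driven by
    pairwise normalized gene similarities (weighted adjacency graphs of
    reduced genomes, optimization over maximal matchings in the gene
    similarity graph), an exact branch-and-bound solver for the
    associated integer linear program together with an LP-format model
    exporter, brute-force reference solvers, hardness-gadget and
    rearrangement-simulation instance generators, and a command-line
    interface. Genomes are read and written in a UniMoG-style signed
    gene-order format; similarities are plain three-column TSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
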