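Package: plastarch
Title: Comparative Architecture Analysis of Chloroplast Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of annotated chloroplast
    (plastid) genome architecture in green algae. Reads annotated
    circular genome records from GenBank flatfiles, normalizes gene
    nomenclature against a shipped conserved-gene catalog, and computes
    per-genome architecture metrics (A+T content, gene counts,
    intergenic fraction, repeat fraction) together with detection of
    the large inverted repeat and the quadripartite IR/LSC/SSC
    partition. Compares genomes by signed gene order: conserved signed
    adjacency pairs, ancestral-pair selection against outgroups, and
    maximal colinear synteny blocks between circular gene orders.
    Compares conserved-gene repertoires across taxa and maps gene and
    inverted-repeat losses onto a fixed rooted species tree under Dollo
    parsimony (single gain, minimum losses). A seeded simulator evolves
    chloroplast-like genomes along a tree by inversions, gene losses
    and inverted-repeat loss, so every stage of the pipeline can be
    exercised against planted truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
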