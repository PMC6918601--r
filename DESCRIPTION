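Package: molscaf
Title: Linked-Read and Hi-C Super-Scaffolding into Chromosomal Pseudomolecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly toolkit for large plant genomes. Reconstructs 10X
    Chromium molecules from barcoded read-pair alignments, detects and breaks
    chimeric scaffolds from drops in physical molecule and Hi-C link coverage,
    joins corrected scaffolds into super-scaffolds with a minimum-spanning-tree
    link graph, anchors sequences to chromosomes with genetic-map markers, and
    orders and orients super-scaffolds into pseudomolecules guided by Hi-C
    contact decay, with directionality-bias diagnostics and a curation-edit
    interface. Includes a seeded simulator that produces truth genomes and all
    evidence tables so the whole pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    Biostrings,
    BiocGenerics,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
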