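Package: genecontext
Title: Conserved Gene Neighborhoods, Domain Architectures and Phyletic Spreads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Comparative-genomics engine for mining conserved genomic
    contexts around protein families across many annotated genomes.
    Builds ordered N-to-C protein domain architectures from domain-scan
    hit tables (resolving overlaps and collapsing tandem repeats),
    extracts and canonicalizes gene-neighborhood windows around family
    homologs with strand-change markers, clusters contexts into
    conserved neighborhoods under explicit species thresholds,
    reconstructs domain proximity networks with frequency-based node
    retention, and summarizes phyletic spreads over a two-level
    taxonomy. Ships a synthetic-genome generator with planted operons,
    fusions, tandem repeats, paralog dyads and lineage-restricted
    families, plus a ground-truth manifest for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
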