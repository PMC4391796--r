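Package: barcodegap
Title: Distance-Based Species Delimitation from DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular operational taxonomic unit (MOTU) delimitation
    from aligned DNA barcode data, built around the barcode-gap logic used in
    aquatic invertebrate barcoding surveys. Computes Kimura two-parameter
    pairwise distances with explicit gap and saturation handling, collapses
    near-identical haplotypes, partitions sequences into lineages by
    single-linkage distance thresholds, re-implements Automatic Barcode Gap
    Discovery (recursive gap detection over a prior grid), builds
    neighbor-joining trees with column-resampling bootstrap support,
    constructs median-joining haplotype networks with single-step indel
    coding, and compares mitochondrial against nuclear partitions over shared
    specimens. A seeded two-marker sequence simulator with known lineage truth
    supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
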