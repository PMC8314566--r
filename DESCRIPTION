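Package: fibroinArch
Title: Seed-Extension Curation and Repeat-Motif Architecture of Silk
    Fibroin Genes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing and analysing the highly repetitive
    heavy-chain fibroin (H-fibroin) genes of silk-producing insects such as
    bagworm moths (Lepidoptera: Psychidae). Implements seed-extension
    curation of repetitive genes from short reads (exact large-k-mer read
    harvesting, position-weight-matrix consensus calling, repeat-entry
    termination), segmentation of the H-fibroin repetitive domain into its
    four motif regions (poly-alanine with a central glutamic acid, pure GA,
    isoleucine/valine linker, serine-containing GA), motif-length and
    amino-acid-composition statistics, predicted crystalline-fraction
    scoring, and the statistics linking crystalline/amorphous balance to
    fibre mechanics. A synthetic-data module generates fibroin genes, short
    reads and mechanics tables with known ground truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'curation.R'
    'fibroinArch-package.R'
    'io.R'
    'motif-architecture.R'
    'pipeline.R'
    'silk-stats.R'
    'synthetic-data.R'
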