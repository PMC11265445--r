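Package: repliconview
Title: Wrapped In-Line Genome Diagrams with Semantic Zooming, Comparative
    Alignment and Data Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic rendering library for bacterial genome
    browsing. Lays out genes, transcription units, transcription start
    sites, terminators and transcription-factor binding sites as a
    book-style wrapped in-line diagram with semantic zooming, supports
    anchor-preserving zoom and pan, gene/product/coordinate search,
    origin-spanning sequence selection with translation and FASTA export,
    ortholog-anchored comparative alignment of multiple genomes with a
    recycled twelve-color palette, and quantitative GFF data tracks in
    three display styles. Emits static SVG instead of an interactive
    canvas; includes a seeded synthetic-genome generator so every
    operation is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    IRanges,
    S4Vectors,
    rtracklayer,
    xml2,
    grDevices,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
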