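Package: cactascan
Title: Structural Annotation of CACTA Transposable Elements in Genome Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and structural characterization of CACTA (EnSpm/CMC)
    DNA transposons in genome contigs. Provides CACTA-anchored terminal
    inverted repeat (TIR) pairing, subterminal repeat (subTIR) periodic-unit
    annotation, target-site-duplication checks, self-dot-plots,
    conserved-domain-architecture (CDA) typing from DANTE-style protein-domain
    hit tables, captured gene-fragment and tandem satellite-array annotation,
    and transposase comparative analysis (p and Tamura 1992 distances,
    neighbor-joining trees, nearest-reference clade assignment). A synthetic
    element generator with exact ground truth makes every detector testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
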