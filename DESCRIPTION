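Package: mitescan
Title: Discovery and Comparative Analysis of Miniature Inverted-Repeat
    Transposable Elements in Small Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo discovery of miniature inverted-repeat transposable
    elements (MITEs) in small (viral-scale) genome assemblies, and the
    downstream analyses used to characterize them: terminal inverted repeat
    (TIR) detection, family clustering and consensus building, target site
    duplication (TSD) calling, superfamily classification from TIR/TSD
    signatures, library-based copy annotation and per-copy divergence,
    paralogous empty-site and orthologous-site presence/absence analysis,
    horizontal-transfer screening by identity and coverage, putative
    autonomous-partner linkage through shared termini and transposase-scale
    open reading frames, and neighbor-joining phylogenies of element copies
    with bootstrap support. Includes a synthetic-genome generator that
    plants MITE families with known ground truth for end-to-end recovery
    scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
SystemRequirements: mafft
Config/testthat/edition: 3
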