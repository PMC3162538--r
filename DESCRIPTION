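Package: ssrmine
Title: Microsatellite Mining, ORF Placement and SSR Marker Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects perfect and compound microsatellites (SSRs) in nucleotide
    sequence under MISA-style thresholds, assigns canonical motif classes by
    cyclic rotation, predicts open reading frames with a longest- or
    innermost-ATG rule, and classifies each SSR as inside, outside or bridging
    an ORF. Provides the downstream statistical chain used in SSR marker
    development studies: repeat-type distribution tables and densities per
    Mbp, chi-square goodness-of-fit of motif distributions against
    base-composition expectations, inside/outside-ORF placement tests, a
    polymorphism index computed from F2 screening matrices, segregation
    distortion tests, cross-taxa transferability summaries, and per-locus
    diversity statistics (allele counts, size ranges, unbiased expected
    heterozygosity). A seeded synthetic-data generator produces sequence with
    planted SSRs and ORFs plus screening, transferability and genotype tables
    with known ground truth, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
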