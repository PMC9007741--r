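Package: txharmony
Title: Harmonization of Transcript Annotation Across Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converging two gene annotation sets on a single
    representative ("Select") transcript per protein-coding gene. Implements
    per-gene transcript selection under a composite-score scheme and a
    ranked-binary hierarchical scheme, identifier-independent transcript
    matching by CDS and exon structure, evidence-driven standardization of
    5' and 3' transcript ends from CAGE and poly(A) site counts (the
    "longest strong" rule), promoter-signature analysis of transcription
    start sites (positional nucleotide frequencies and PWM motif scanning
    with exact p-values), and nomination of supplementary clinical
    transcripts for genes where pathogenic variants fall in conserved
    coding exons absent from the Select transcript. A deterministic
    synthetic-locus generator emits genomes, paired annotations, and all
    evidence tracks with known ground truth so the whole workflow is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    stats,
    utils,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
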