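Package: tepool
Title: Transposable Element Polymorphism Detection and Frequency
    Estimation from Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects transposable element (TE) insertions and absences in
    pooled paired-end DNA sequencing data relative to a reference genome.
    Discordant read pairs with one uniquely mapped anchor localize
    sample-specific insertions; read pairs spanning longer-than-expected
    distances reveal reference TEs absent from the sample. Soft-clipped
    reads refine event junctions to base-pair resolution and yield target
    site duplication lengths, and the ratio of supporting to
    reference-consistent read pairs estimates each event's population
    frequency. Ships a paired-end read and structural-variant simulator,
    a truth-set evaluator, and population analytics (Mendelian frequency
    change, Wright-Fisher drift tails, junction sequence composition) so
    the whole pipeline can be benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
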