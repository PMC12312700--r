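Package: epirhythm
Title: Nonparametric Circadian Rhythm Detection and Cross-Condition
    Comparison for Transcriptome and Promoter Acetylation Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects circadian rhythms in gene expression time courses with
    an exact-null nonparametric scan (Kendall/Jonckheere-Terpstra statistics
    against cosine reference waveforms over an 18-30 h period window),
    compares rhythm amplitude and phase across experimental conditions
    (e.g. conventionally raised vs germ-free vs tissue-specific knockout),
    attributes rhythmicity to upstream regulators through a two-level set
    comparison funnel, quantifies promoter histone-acetylation signal from
    aligned ChIP-seq reads, and tests transcription-factor motif and
    gene-set over-representation in promoter windows with Fisher and
    hypergeometric statistics plus kappa-score term networks. A synthetic
    data generator with full ground truth exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
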