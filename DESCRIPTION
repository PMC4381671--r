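Package: ccgpipe
Title: Circadian Clock-Controlled Gene Analysis from Count Time Courses
Version: 0.1.0
Authors@R: person("ccgpipe", "Maintainers", email = "ccgpipe@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for circadian transcriptomics in organisms with
    a short free-running period (~22 h), built around paired RNA-seq and
    RNAPII-S2P ChIP-seq time courses sampled every 2 h in constant darkness.
    Provides exonic and 3'-terminal-window read counting, overlap-contamination
    (influence factor) and expression filters, median-of-ratios normalization,
    a calibrated harmonic-regression rhythm detector over an 18-26 h period
    range with a dual with/without-t0 protocol, negative-binomial sine fitting
    at a fixed 22 h period for phase and fold-amplitude estimation,
    shuffle-based amplitude- and coverage-stratified false discovery rates,
    a two-sided negative-binomial exact test for condition pairs, dawn/dusk
    phase classification and transcription-vs-RNA concordance grouping, plus a
    seeded synthetic-data generator with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
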