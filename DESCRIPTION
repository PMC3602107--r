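Package: siteMarks
Title: Histone Mark Enrichment and Aggregate Profiles Around
    Transcription Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of ChIP-seq histone mark tag patterns around
    transcription factor binding sites (TFBSs): per-site Poisson
    enrichment calls against a dynamic local background estimated from a
    control sample at 1/5/10 kb scales, enrichment-proportion curves over
    window sizes, control-subtracted strand-oriented aggregate signal
    profiles with shape characterisation (bimodal/unimodal modes,
    asymmetry, nucleosome-free regions), stratification of sites by TSS
    distance and transcription factor role, and pairwise Spearman
    correlation of marks over genome bins and site windows.  Includes a
    seeded synthetic ChIP-seq generator with planted peaks, matched
    control and ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
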