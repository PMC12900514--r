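Package: polterm
Title: RNA Polymerase I Pausing, Premature Termination, and CRAC Occupancy Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study premature termination of transcription (PTT) by RNA
    polymerase I on the yeast rDNA unit. Implements a single-molecule elongation
    model in which site-specific pausing is coupled to termination hazard, its
    closed-form steady state (survival, flux, occupancy, abortive spectrum,
    full-length rate), and a CRAC-like read simulator with UMIs and PCR
    duplication. Provides the downstream analytics used for 3'-end occupancy
    profiling: PCR-duplicate removal keyed on (start, end, UMI), per-base 3'-end
    coverage with hits-per-million normalization, replicate min-max envelopes,
    conservative envelope differences, low-coverage-masked log2 ratios,
    per-region summed-frequency statistics, cumulative-distribution shift
    metrics, and slot-blot/northern densitometry arithmetic (5S normalization,
    window integration, fold-change statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
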