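Package: respalign
Title: Alignment of Respiration to Task Events via Phase-Locking and
    Circular Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for event-locked respiratory dynamics in
    trial-based behavioral experiments. Segments continuous respiration
    traces into breathing cycles, flags atypical cycles, constructs a
    piecewise-linear respiratory phase, epochs the phase around stimulus
    onsets, and quantifies alignment with the phase-locking vector
    strength (plvs). Inference uses a time-shift surrogate null with
    max-over-time correction, cluster-based sign-flip permutation tests
    on condition contrasts, plvs slopes around stimulus onset, circular
    phase statistics with randomization tests, cycle-duration contrasts,
    and rank correlations between respiratory and behavioral condition
    differences. Includes a synthetic-data generator that emulates
    blocked-deadline and cued-value paradigms with controllable von
    Mises phase coupling, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rlang,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
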