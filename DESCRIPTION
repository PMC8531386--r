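Package: graphrely
Title: Test-Retest Reliability of EEG Brain-Graph Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Band-resolved functional connectivity from multichannel
    resting-state EEG (weighted phase lag index and spectral coherence from
    Welch-style segment cross-spectra), weighted global graph metrics
    (clustering coefficient, characteristic path length, cross-band
    small-world index), and test-retest reliability analysis: single-rating
    absolute-agreement two-way intraclass correlation with F-based
    confidence intervals, standard error of measurement and coefficient of
    variation with bootstrap intervals, paired bootstrap effect-size
    comparison of reliability across conditions, and two-by-two
    repeated-measures ANOVA. Includes a synthetic generator of coupled
    band-limited oscillatory recordings with controllable between-session
    consistency for end-to-end validation, plus EDF and delimited-matrix
    recording I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
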