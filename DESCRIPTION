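Package: counterphase
Title: Detection of Counter-Phase Alternatively Polyadenylated Isoforms in
    Circadian Expression Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling and mining counter-phase oscillations of
    alternatively polyadenylated transcript isoforms in circadian expression
    data. Implements the two-isoform transcription/decay harmonic model and
    its analytic amplitude/phase solution (the "molecular rectifier"), a
    synthetic microarray time-course generator with planted phase structure,
    maximum-entropy bootstrap phase assignment with permutation rhythmicity
    tests, within-gene probe-pair phase-difference histograms, and a Poisson
    goodness-of-fit test of the stochastic-decay null with asymptotic and
    Monte Carlo p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
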