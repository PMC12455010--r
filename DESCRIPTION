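Package: kvinact
Title: Inactivation-Delay Heterogeneity Analysis for Voltage-Gated K+ Channel Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cell-to-cell heterogeneity in the N-type
    inactivation delay of voltage-gated potassium channels (Kv3.4 and
    related channels) from whole-cell voltage-clamp cohorts. Provides a
    forward simulator of step-protocol current families (Hodgkin-Huxley
    activation gating combined with an Erlang-chain "ball-and-chain"
    inactivation latency, glycoform mixtures, leak and baseline noise,
    realistic recording-quality metadata), a portable delimited-text cohort
    format, two-stage patch-clamp quality-control filtering, extraction of
    the inactivation width at 70 percent of the normalized peak current,
    Tukey boxplot whisker-span heterogeneity statistics with condition
    comparisons, and a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
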