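Package: kdsync
Title: Temporal Cluster, Quiet-Period and Cross-Site Synchrony Analysis
    for Disease Onset-Date Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection of temporal clusters (high 7-day case density) and
    quiet periods (anomalously long zero-case gaps) in per-site case
    onset-date series, with percentile-based local definitions,
    trend- and seasonality-respecting Monte Carlo null ensembles, and
    pairwise plus ensemble cross-site overlap significance testing.
    Includes a synthetic onset-series generator with controllable
    seasonality, long-term trend, injected bursts and cross-site burst
    synchrony, so the whole pipeline is testable without confidential
    patient records. Developed with Kawasaki disease surveillance series
    in mind but applicable to any sparse event-onset time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
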