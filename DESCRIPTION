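Package: phasentropy
Title: Temporal Complexity of Dynamic Phase-Synchrony Brain Networks
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of the temporal complexity of time-resolved
    functional brain networks. From multichannel band-limited time series the
    package builds instantaneous phase-synchrony graph sequences (Hilbert
    analytic signal, |sin| phase-difference tensors, binary thresholding),
    computes time-resolved clustering and participation coefficients with
    Louvain community detection, quantifies the temporal complexity of these
    metric time series with sample entropy (SampEn), and runs group-level
    statistical comparisons including phase-randomized surrogate contrasts,
    PCA-based network definition, network ANOVA and density threshold sweeps.
    A synthetic-data module generates band-limited coupled-oscillator networks
    with planted modular phase coupling and segregation/integration state
    switching, plus canonical reference signals (sine banks, white noise,
    fractional Brownian motion) for entropy benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
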