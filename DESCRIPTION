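Package: dynstates
Title: Dynamic Integrated/Segregated Brain States and Structural Control Energy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for time-resolved functional brain states and the
    structural network control energy of transitions between them. Computes
    sliding-window dynamic functional connectivity from parcel-level BOLD
    timeseries, detects per-window community structure under signed asymmetric
    modularity (Louvain), summarises each window by its cartographic profile
    (participation coefficient by within-module degree z-score joint histogram),
    clusters windows into Integrated and Segregated states, and derives temporal
    metrics (fraction of time, dwell time, transitions). From subject structural
    connectomes it solves the continuous-time linear-quadratic fixed-endpoint
    control problem to obtain minimal transition and persistence energies and
    their nodal decomposition, correlates nodal energy with cortical hierarchy
    and with receptor-density maps using spatial (spin) permutation tests, and
    compares state connectomes between groups with the network-based statistic.
    Includes a synthetic-cohort generator (regime-switching multivariate normal
    BOLD, modular weighted connectomes with planted hub weakening, spatially
    autocorrelated nodal maps) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    stats,
    utils,
    jsonlite,
    yaml,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
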