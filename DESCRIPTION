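Package: netswitch
Title: Switching Rates of Dynamic Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the temporal stability of dynamic functional brain
    networks from regional time series. Builds sliding-window Fisher
    z-transformed Pearson connectivity layers, detects time-varying modular
    structure by generalized Louvain optimization of multilayer (temporal)
    modularity with ordinal inter-layer coupling, and summarises node,
    subnetwork and global switching rates averaged over repeated stochastic
    partitions. Includes a seeded synthetic-cohort generator with planted
    module-switching structure, covariate-adjusted group statistics (ANCOVA,
    paired t tests, Spearman and partial Pearson correlations,
    Benjamini-Hochberg false-discovery-rate correction), and an end-to-end
    reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    yaml
Config/testthat/edition: 3
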