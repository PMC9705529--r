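Package: dynmodnet
Title: Dynamic Modular Brain Networks from Band-Limited ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses dynamic modular cortical networks from
    band-limited region-of-interest (ROI) time series. Sliding-window
    weighted phase lag index (WPLI) connectivity is assembled into weighted
    multilayer graphs, functional modules are found by repeated generalized
    Louvain multilayer-modularity maximization, and module-allegiance
    metrics (flexibility, integration, recruitment, node-to-system density)
    are summarized per large-scale functional system and compared across
    experimental conditions with paired statistics (paired t, Cohen's dz,
    Benjamini-Hochberg FDR, Anderson-Darling normality, analytic power).
    Includes a seeded synthetic ROI-time-series generator with planted,
    time-varying module structure for validation, and an optional
    signal-conditioning front end (Butterworth band-pass, line-noise notch,
    epoching, EDF reading) for continuous recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    nortest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
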