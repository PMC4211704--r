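Package: connstab
Title: Distance Dependence and Stability of Task-Driven Functional
    Connectivity Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether task- or group-driven changes in
    functional connectivity depend on the Euclidean distance between
    regions. Builds Fisher-z connectivity matrices from multi-subject,
    multi-condition region-of-interest time series, fits a mean-centered
    task partial least squares (PLS) model to the vectorized connectomes
    with permutation tests of latent variables and bootstrap estimation
    of edge salience reliability, and assesses distance dependence of
    edge-level change with a nonparametric independent-pairs resampling
    null that respects the non-independence of correlation-derived
    edges. Includes Louvain module and hemisphere/homotopy edge
    stratification, a homotopic-stability exceedance test, a synthetic
    data generator with known ground truth for parameter-recovery
    testing, and a reader for connectivity matrices stored in MAT-v5
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
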