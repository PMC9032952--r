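Package: statetrans
Title: State-Transition Modeling of Leukemia Development from Time-Series
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the development of acute myeloid leukemia as a
    state-transition of the transcriptome: a particle undergoing Brownian
    motion in a double-well quasi-potential over a one-dimensional
    state-space built by singular value decomposition of time-series
    expression data.  Provides a synthetic-cohort generator with ground
    truth, preprocessing (CPM/log2/centering), state-space construction and
    projection, critical-point estimation by exact one-dimensional K-means
    with a Boltzmann-ratio transition point, diffusion estimation from mean
    squared displacement, a conservative Fokker-Planck solver for
    time-to-leukemia prediction, survival-curve comparison by the log-rank
    test, critical-point-aligned differential expression with event
    classification and loading-based contribution vectors, expression
    dynamics pattern discovery, and comparison of state-spaces built from
    different feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    limma,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
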