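Package: spikegraph
Title: Spike Sorting by Template Deconvolution and Bipartite Modularity Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spike-sorting pipeline for extracellular multichannel
    recordings on high-density probes. Implements on-demand preprocessing
    (common average referencing, FFT-domain high-pass filtering matched to a
    Butterworth response, local ZCA channel whitening), probe drift
    estimation and kriging-based alignment, matching-pursuit template
    deconvolution with rank-3 template factorization and
    background-subtracted PC features, landmark-based bipartite modularity
    graph clustering with a hierarchical merging tree, and curation driven
    by cross-correlogram refractoriness and projection bimodality. A
    built-in simulator renders synthetic drifting recordings with ground
    truth, and benchmarking utilities score sorted output against that
    truth. Results are written as Phy-compatible array files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    Rcpp,
    tibble,
    dplyr,
    jsonlite,
    rlang,
    yaml,
    signal
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
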