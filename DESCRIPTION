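Package: restgraph
Title: Graph-Theoretic Analysis of Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for resting-state functional-connectivity
    graph analysis: wavelet sub-band filtering of regional BOLD time
    series, Pearson correlation adjacency matrices, thresholded binary
    graphs, graph-theoretic network measures (degree, strength, path
    length, global and local efficiency, clustering, betweenness
    centrality, small-worldness, modularity via Louvain community
    detection, and participation coefficients), degree-preserving random
    null models, and paired nonparametric pre/post comparison with
    multiple-comparison correction. Includes a synthetic-data generator
    that plants known modular connectivity structure and session-wise
    connectivity changes, so that every stage of the pipeline is testable
    end to end without access to scanner data, plus optional atlas-based
    parcellation of 4-D volumes into regional mean time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
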