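Package: phenotraj
Title: Temporal Phenotypes from Record-Level Clinical Data via Topology and
    Pseudo-Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers disease-progression phenotypes from cross-sectional,
    record-level clinical observations. Builds a Mapper-style topological
    network over encounters (overlapping two-dimensional cover on lens
    functions, per-bin single-linkage clustering), detects communities by
    modularity maximisation, extracts progression trajectories with a
    time-weighted minimum spanning tree, and assigns individual subjects to
    mined trajectories by Jaccard similarity. Independently reconstructs
    progression dynamics with bootstrapped pseudo-time-series fed to an
    order-1 autoregressive Gaussian hidden Markov model fitted by EM.
    Includes a fully specified synthetic cohort generator and a five-state
    benchmark simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
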