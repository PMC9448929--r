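Package: connectotype
Title: Architecture Typing and Lesion Vulnerability of Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Groups populations of brain structural-connectivity matrices into
    architecture types by resolution-tuned modularity on subject-similarity
    matrices, simulates each network's neural dynamics with Kuramoto phase
    oscillators, and quantifies differential vulnerability to cumulative
    targeted hub lesions. Includes a synthetic connectome population
    generator with planted architecture archetypes, weighted graph metrics
    (global efficiency, shortest path length, betweenness, clustering),
    coupling sweeps with critical-coupling estimation, and ANOVA plus
    Tukey-Kramer group reporting.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
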