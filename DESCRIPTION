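Package: funcarto
Title: Functional Cartography of Dynamic Network Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping the dynamic community structure of
    multi-condition functional networks. Converts multi-condition node
    time series into stacks of Fisher-z functional connectivity
    matrices, detects communities across conditions with a generalized
    Louvain maximization of categorical multislice modularity,
    summarizes ensembles of partitions as a module allegiance matrix,
    and computes flexibility, recruitment and integration statistics at
    the region and system level. Node-sets ("systems") are classified
    into nine dynamic network roles (ephemeral/unstable/stable x
    loner/connector/integrator) against a size-preserving permutation
    null model. Includes a planted-partition synthetic data generator
    so the full pipeline is testable without external data, a (gamma,
    omega) resolution/coupling grid search with z-Rand partition
    similarity diagnostics, plain-text readers and writers for matrix
    stacks and system maps, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
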