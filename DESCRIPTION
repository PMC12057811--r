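Package: grnsparse
Title: Topology-Based Sparsity Selection for Gene Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects the single best gene regulatory network (GRN) from a
    family of networks inferred at varying sparsities, using two metrics built
    on the scale-free topology hypothesis: a chi-squared goodness-of-fit of the
    out-degree distribution to a discrete power law (with an approximate
    maximum-likelihood exponent and the Hurwitz zeta normalisation) and the
    Pearson correlation of log-frequency versus log-degree with its p-value.
    Includes a steady-state perturbation-response simulator with controlled
    signal-to-noise ratio, P-based network inference methods (LASSO path,
    Zscore, LSCON, and an optional tree-ensemble method), F-beta accuracy
    scoring against gold-standard networks, and a reproducible benchmark
    harness over sparsity, noise and inference method.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
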