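Package: ChoquetFusion
Title: Multi-View Consensus Classification with the Choquet Integral
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-level fusion of multi-view (multi-camera) classifier
    probability outputs using the discrete Choquet integral with respect to a
    symmetric power fuzzy measure. For each class, the per-view membership
    probabilities are aggregated and the consensus class is the maximum fused
    response. Includes macro-averaged precision/recall/F-beta evaluation, a
    Dirichlet-based simulator of clean and degraded multi-view softmax outputs
    for robustness studies, CSV/JSON interchange for score matrices,
    predictions and reports, and a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'ChoquetFusion-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'measures.R'
    'aggregation.R'
    'consensus.R'
    'metrics.R'
    'simulator.R'
    'io.R'
    'show-methods.R'
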