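Package: connclass
Title: Functional Connectome Classification with Graph Metrics and
    Multiple Kernel Learning
Version: 0.1.0
Authors@R:
    person("connclass", "maintainers", email = "maintainers@connclass.org",
           role = c("aut", "cre"))
Description: Construction and classification of functional brain connectomes
    from region-of-interest time series. Builds Pearson correlation networks,
    binarizes them over a sparsity-threshold grid, computes global, nodal and
    module-level graph metrics (small-worldness, modularity, participation
    coefficient, within-module degree, hub detection), selects features by
    edge-wise t-tests with network-based statistic permutation testing and
    group-LASSO logistic regression, and classifies groups with a multiple
    kernel learning support vector machine under nested leave-one-out cross
    validation. Includes a synthetic two-group cohort generator with planted
    connectivity effects so the full pipeline is testable without imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
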