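Package: tdaracne
Title: Time-Delayed Mutual Information Inference of Gene Regulatory Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reverse engineering of small directed gene regulatory networks
    from short time-course expression data. Candidate regulations are scored
    by time-delayed mutual information estimated with a kernel density
    smoother on a fixed grid after a rank-based copula transform; the
    significance threshold is auto-calibrated by a stationary block
    bootstrap of the series, and indirect edges are pruned with a two-pass
    Data Processing Inequality rule. Includes a linear stochastic
    difference-equation simulator of random well-defined networks for
    benchmarking, and directed-edge precision/recall/F evaluation against a
    gold standard.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    KernSmooth,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: NetworkInference, TimeCourse, GeneExpression, GraphAndNetwork
RoxygenNote: 7.3.3
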