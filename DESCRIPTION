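Package: cytocausal
Title: Causal Discovery from Perturbed Single-Cell Signaling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Local causal discovery and shift-intervention network inference
    for perturbation experiments on single-cell signaling data, such as gated
    mass-cytometry panels of phosphoprotein markers. Implements conservative
    local causal discovery (CLCD) over activator/protein trios with
    dual-threshold conditional-independence testing and replicate-support
    aggregation; connectivity-matrix estimation from inhibitor-dosage
    environments treated as shift interventions, via joint diagonalization of
    covariance differences with parametric-bootstrap diagnostics and stability
    selection; exact Bayesian Gaussian-equivalent (BGe) scoring of candidate
    trio networks to test predictions for consistency in independent data
    sets; and ranked-precision evaluation against a directed pathway ground
    truth. A synthetic-data generator reproduces the activator x inhibitor x
    dosage x replicate study layout from known linear causal models, so every
    stage is testable without access to the original measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
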