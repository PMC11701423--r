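Package: pgicp
Title: Perturbation Graphs and Invariant Causal Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Causal discovery from combined observational and
    interventional (multi-context) data. Simulates linear Gaussian
    structural equation models under hard and soft interventions, builds
    perturbation graphs from per-context and pooled conditional
    correlations, applies the minimum-coefficient transitive-reduction
    heuristic (and exposes the counterexample showing it is
    inconsistent), and estimates direct causes by conditional invariant
    causal prediction with an intersection-of-accepted-sets estimator,
    including a sequential Chow-test variant for time series split into
    regime blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
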