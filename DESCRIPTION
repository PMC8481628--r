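Package: procrasim
Title: Simulating Procrastination with a Goal-Based Reduced Successor
    Representation Agent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulator of procrastination as a consequence of
    inaccurate value approximation under a dimension-reduced successor
    representation. A student-like agent traverses a short task chain choosing
    between costly progress ("GO") and free delay ("STAY"), learning
    approximated state values as a linear function of goal-based reduced-SR
    features through temporal-difference learning, while a tabular
    temporal-difference tracker estimates the true policy-dependent values in
    parallel. Includes a forced-progress training phase followed by a
    free-choice phase, elapsed-time penalty / unpredictable regret / slow
    representation-update model variants, deterministic multi-run ensembles
    with per-run seed substreams, parameter sweeps, tidy ensemble summaries,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
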