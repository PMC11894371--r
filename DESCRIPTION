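Package: stressrep
Title: Discrete-Individual Repeatability Metrics for Stress-Response Curves
Version: 0.1.0
Authors@R: person("stressrep", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Computes and compares three metrics of discrete-individual
    repeatability for replicated hormone stress-response curves: profile
    repeatability (a bounded [0,1] score combining per-timepoint variance
    across replicates, curve crossings, and an interpolation penalty),
    generalized Kullback-Leibler divergence over ordered successive
    replicate curves, and HPA flexibility (the root mean square of
    successive differences of per-curve means). Includes tie-aware
    competition ranking of individuals, pairwise Pearson correlation of
    rank vectors with significance coding, a replicate-subsampling
    combination analysis against the consensus score, a seeded synthetic
    curve generator spanning a repeatability gradient, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
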