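Package: morphspace
Title: Time-Invariant Working-Memory Subspaces in Morphing Neural Population Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying low-dimensional linear subspaces of neural
    population activity that carry time-invariant working-memory information
    even when the full population code changes ("morphs") across task epochs.
    Provides rate-based recurrent network simulators (a ring bump-attractor
    model and a linear eigenvector-subspace model) of a delayed-saccade task
    with an intervening distractor, preprocessing into z-scored
    pseudo-population activity and PCA full spaces, a Frobenius-norm subspace
    optimizer, cross-temporal linear-discriminant decoding with LP summary
    statistics, state-space cluster-shift and trajectory-parallelism (PLV)
    statistics, bootstrap-overlap inference with Hedges' g effect sizes, and a
    location-by-epoch ANOVA classification of neurons into classical, linear
    mixed, and non-linear mixed selectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
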