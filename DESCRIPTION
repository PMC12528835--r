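Package: svdecoder
Title: Subjective Value Modeling and Multivoxel Pattern Decoding Under
    Risk and Ambiguity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for model-based analysis of risky decision-making and its
    neural representation. Implements a modified power-utility model of
    subjective value under known-risk and ambiguity with constrained
    maximum-likelihood preference estimation, a generator for synthetic
    cohorts (task schedules, choices, trial-wise multivoxel beta patterns and
    BOLD runs with controllable signal fidelity), a first-level GLM engine
    with parametric subjective-value modulators, leave-one-run-out
    support-vector decoding of subjective-value level within and across
    uncertainty contexts with bootstrap label balancing, and permutation-based
    group inference including a network-level "widespreadness" index.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
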