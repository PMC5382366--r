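Package: boolscape
Title: Attractor Landscapes and Reversion Analysis for Weighted-Sum Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models gene regulatory networks as Boolean networks with a
    weighted-sum update rule, quantifies their attractor landscapes from
    exhaustive or Monte-Carlo sampled initial states, and scores each
    landscape against a configurable phenotype rubric (the "normal-like
    score" over proliferation, EMT and stemness marker rules).  On top of
    the landscape machinery it provides systematic single- and double-node
    perturbation scans with synergy classification, greedy extraction of
    functional network motifs with activity-stability profiling, and
    robustness trajectories along sequences of accumulating mutations.
    Includes a synthetic network generator, a set of curated small
    fixtures with exhaustive oracles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
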