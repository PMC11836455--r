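Package: sernarc
Title: Agent-Based Simulation of Narcissistic Self-Esteem Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an agent-based model of self-esteem regulation in
    grandiose narcissism. Agents on a grid lose self-esteem over time
    (leakage), compare it with a slowly habituating need for admiration
    (tolerance development), and regulate the resulting shortfall through
    intra-individual boosts or the inter-individual strategies admiration and
    rivalry, whose behaviour-initiation thresholds can adapt through
    contingent reinforcement and non-contingent environmental over- or
    devaluation (the learning variant of the model). Ships reproducible
    experiment recipes for threshold sweeps, learning environments, learned
    "adult" agents, and trait-group comparisons, together with trajectory
    summaries, tidiers, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
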