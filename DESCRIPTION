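Package: selexr
Title: Analysis and Simulation of Cell-SELEX Sequencing Rounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-throughput sequencing of aptamer
    selection (SELEX) rounds: adapter-delimited variable-region extraction
    with length filters, greedy mismatch-radius clustering of pooled unique
    sequences with ambiguous-tie handling, round-over-round enrichment
    percentages and per-cluster abundance trajectories, Northern-blot band
    ratio and internalization quantification, pairwise global-alignment
    identity of variable regions, and a forward simulator of selection
    rounds with multiplicative selection, finite sequencing depth and
    per-base error, so every stage of the pipeline can be exercised on
    synthetic data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
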