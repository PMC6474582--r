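Package: mutscape
Title: Mutational Landscapes of Digital Organisms in Changing Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale digital-evolution system for studying how cyclically
    changing environments reshape the local mutational landscape of evolving
    self-replicating programs. Provides a deterministic 26-instruction virtual
    CPU and genome substrate, the Logic-77 catalog of 1-3 input bitwise logic
    tasks, static and fluctuating (benign/harsh) reward schedules, evolution on
    a toroidal grid with substitution mutation, ancestry tracking (phylogenetic
    depth, most recent common ancestor, selective sweeps, vestigial sites),
    exhaustive one-step and non-reversion two-step mutational-neighborhood
    surveys, genomic and phenotypic diffusion-rate metrics with
    expected-fitness aggregation across environments, per-site population
    entropy, task discovery and performance counters, and the accompanying
    non-parametric statistical comparisons and regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    broom
Config/testthat/edition: 3
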