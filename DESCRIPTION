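Package: condlab
Title: Frequentist and Default Bayesian Analysis of Differential
    Conditioning Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis engine for differential threat-conditioning
    experiments in which conditioned responses to a reinforced stimulus
    (CS1) and an unreinforced stimulus (CS2) are compared within
    participants, optionally across two groups. Computes descriptive
    statistics, paired and independent-samples t-tests with Cohen's d,
    and the default (Jeffreys-Zellner-Siow) Bayes factor with a
    Cauchy prior on the standardized effect size, including a
    sensitivity (robustness) analysis over the prior scale. Results are
    rendered as an automatic Markdown report with optional
    evidence-category interpretation, plots of condition means and of
    Bayes-factor robustness, and machine-readable JSON/CSV output. A
    command-line entry point drives the full pipeline from delimited
    data files or from summary statistics, and a seeded generator
    produces correlated two-condition datasets for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    foreign,
    haven,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
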