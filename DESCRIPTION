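Package: mptstab
Title: Reliability and Stability of Multinomial Processing Tree
    Parameters for the Implicit Association Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate how reliably and stably the cognitive
    processes behind race Implicit Association Test (IAT) responses can
    be measured with multinomial processing tree (MPT) models.  Ships
    the Quad and process-dissociation (PDP) model trees, reads
    trial-level IAT data, fits hierarchical Bayesian latent-trait MPT
    models via JAGS, quantifies between-occasion consistency with
    two-way mixed-effects intraclass correlations, quantifies
    within-occasion reliability by parameter-recovery simulation, and
    synthesizes results across datasets with random-effects and
    multilevel meta-analysis on the Fisher-z scale.  A seeded
    synthetic-data generator with known ground truth lets the whole
    pipeline run end to end without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    metafor,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
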