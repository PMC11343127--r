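Package: proteoturn
Title: Protein Turnover Kinetics and Proteostasis Inference from D2O
    Labeling and Label-Free Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers whether proteome changes between genotypes are driven by
    protein synthesis or degradation, by combining two measurements made on
    the same animals: turnover rates estimated from deuterated-water (D2O)
    metabolic labeling time courses under a first-order homeostasis model,
    and relative abundances from label-free quantification (LFQ). Provides
    per-peptide quality filters and pooled exponential rate fitting, an LFQ
    normalization and imputation workflow with variance-gated differential
    tests, ontology-level aggregation of scaled fold changes with one-sample
    t-tests and Benjamini-Hochberg correction, and quadrant classification
    of each protein or ontology into increased/decreased synthesis or
    degradation. A seeded synthetic-data generator with known ground-truth
    kinetics supports end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
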