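Package: snosite
Title: Sequence-Derived Prediction of Cysteine S-Nitrosylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts cysteine S-nitrosylation (SNO) sites from protein
    sequence. Candidate cysteines are represented by fixed-length peptide
    windows encoded with three sequence-derived feature sets: a 400-dimensional
    aggregation of PSI-BLAST position-specific scoring matrix substitution
    scores, nine segment statistics of predicted secondary structure, and 49
    averaged physicochemical properties. Features are ranked by symmetric
    relative entropy between the class-conditional distributions, an
    incremental feature selection search over ranked prefixes picks the subset
    maximising cross-validated Matthews correlation, and prediction uses a
    k-nearest-neighbour classifier with Euclidean distance. Includes parsers
    for FASTA, PSI-BLAST ASCII PSSM and PSIPRED ss2 inputs, a deterministic
    synthetic-data generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
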