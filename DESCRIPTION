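Package: msmbind
Title: Markov State Model Analysis of Heterogeneous Ligand-Binding Modes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end Markov state model (MSM) pipeline for resolving
    heterogeneous small-molecule binding modes on a protein domain from
    molecular-dynamics trajectory ensembles. Provides protein-ligand
    minimum-distance featurization with quasi-binary contact transforms,
    cross-validated VAMP2 feature scoring, time-lagged independent component
    analysis (tICA), k-means microstate clustering, reversible
    maximum-likelihood MSM estimation with implied-timescale and
    Chapman-Kolmogorov validation, GMRQ hyperparameter selection, PCCA+
    metastable macrostates with core assignment, macrostate populations and
    mean first passage times, adaptive-sampling seed selection, and
    per-residue importance profiling via one-vs-rest random forests and
    Kullback-Leibler divergence. A synthetic-data module generates
    metastable Markov chains and toy bead protein-ligand trajectories with
    analytic ground truth so every stage can be validated exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    randomForest,
    generics,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
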