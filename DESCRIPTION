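Package: rsnvar
Title: Subject-Level Variability of Resting-State Networks and Functional
    Network Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how far each subject's resting-state networks (RSN)
    and functional network connectivity (FNC) deviate from a cohort-common
    pattern within a temporal-concatenation group spatial ICA decomposition.
    Provides mean-activation masking, two-stage PCA reduction with Infomax or
    FastICA unmixing and dual-regression back-reconstruction, three deviation
    metrics (Euclidean distance, Pearson correlation, Kullback-Leibler
    divergence of intensity histograms), component time-course post-processing
    and Fisher-z FNC matrices, weighted global efficiency of the connectivity
    graph, covariate-adjusted group-difference and imaging-genetics
    association testing (per-SNP scans and polygenic risk scores), and a
    fully parameterised synthetic-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
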