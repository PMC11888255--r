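Package: tbsquant
Title: Quantification Pipelines for Theta-Burst Magnetic Stimulation
    Experiments in Slice Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipelines for repetitive magnetic stimulation (rMS)
    experiments in organotypic entorhino-hippocampal slice cultures driven
    by the intermittent theta-burst (iTBS600) protocol: stimulation pulse
    train generation and segmentation, c-Fos positive cell counting with
    batch normalization, miniature EPSC event detection and summary
    statistics, time-lapse dendritic spine trajectory analyses including
    diagonal-averaged unit correlation matrices, a calcium dF/F0 activity
    pipeline (rolling-median detrending, spike detection, AUC, power
    spectra), and the statistical decision layer (Mann-Whitney U,
    chi-square, mixed-model confidence-interval rules). A synthetic-data
    module generates ground-truthed calcium traces, spine trajectories,
    mEPSC current traces and c-Fos-like image stacks so every stage is
    testable without experimental recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp,
    MASS,
    pracma,
    lme4,
    lmerTest,
    EBImage,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
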