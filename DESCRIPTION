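Package: eegdecide
Title: EEG Microstates, Phase-Slope Connectivity and Graph Metrics for
    Emotion-Modulated Decision Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for multichannel EEG recorded
    during blocked decision-making experiments under emotional stimulation.
    Provides a synthetic-data generator with planted ground truth (1/f
    background, condition-dependent event-related potential components,
    lagged inter-channel coupling, behavioral and subjective tables),
    deterministic preprocessing (resampling, zero-phase band-pass filtering,
    average referencing, epoching, amplitude-based epoch rejection),
    event-related potential microstate segmentation by topographic
    atomize-and-agglomerate hierarchical clustering with cross-validation
    model selection, component amplitude/latency measurement with pointwise
    one-way ANOVA, phase-slope-index effective connectivity from
    Hamming-windowed Welch cross-spectra, percolation-threshold
    sparsification with directed weighted graph metrics (characteristic path
    length, global efficiency, clustering coefficient, local efficiency),
    and the statistics layer relating graph metrics to decision accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    signal,
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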