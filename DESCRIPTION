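Package: prelimbic
Title: Prefrontal Spike-Train, Evoked-Response and Touchscreen Behaviour Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for prelimbic-cortex single-unit
    electrophysiology and touchscreen cognitive testing in genetically
    modified mice. Provides extracellular spike detection, PCA-based unit
    sorting and refractory-period quality screening; waveform trough-width
    classification of putative fast-spiking interneurons versus pyramidal
    cells; peri-stimulus time histograms with baseline subtraction,
    paired-click evoked-response amplitude and onset-latency statistics;
    spontaneous discharge-rate comparison under local GABA-A antagonism via
    an unweighted-means two-way ANOVA computed from group summary statistics
    with Newman-Keuls post hoc tests; dependent-variable computation for the
    5-choice serial reaction time task and related touchscreen assays; and a
    synthetic-data generator producing recordings, spike populations and
    behavioural session logs with known ground truth so every stage is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
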