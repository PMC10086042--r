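Package: msnetvar
Title: Spatiotemporal Variability of Microstate-Segmented Dynamic EEG Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes dynamic resting-state EEG brain networks by segmenting the
    recording into transient microstate windows (global field power peaks, polarity-invariant
    modified K-means topographic clustering, template backfitting), estimating a phase-lag-index
    (PLI) functional connectivity network within each window, and summarizing the resulting
    network sequences with per-channel temporal and spatial variability statistics. Network
    sequences can be built from fixed sliding windows (SN), microstate windows (MN), or
    microstate windows partitioned by class (MCN), and compared through a linear-SVM repeated
    stratified cross-validation harness plus channel-wise group statistics (pooled t-tests with
    Benjamini-Hochberg FDR correction) and Spearman correlations with clinical scores. A
    synthetic-data module generates recordings and cohorts with known microstate structure,
    switchable phase-coupling patterns, and injectable group effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
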