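Package: erpdecode
Title: Multivariate Decoding of Visual Spatial Attention from Event-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying attention control and selection with multivariate
    pattern classification of multichannel event-related potentials (ERPs).
    Implements trial-averaged linear support-vector-machine decoding time courses
    for cued visual spatial attention paradigms, the supporting signal-conditioning
    chain (zero-phase Butterworth band-pass, Parks-McClellan notch, least-squares
    FIR low-pass, resampling, baseline correction), moving-window artifact
    screening, N1 attention-modulation measurement, group-level significance
    masking (one-tailed signed-rank tests, false-discovery-rate correction with a
    contiguity filter, bootstrap onset distributions), and between-subject
    brain-behavior linkage (Pearson correlation time courses, Liptak-Stouffer
    meta-analytic combination, and cluster-size permutation tests with shared
    subject shuffles). A synthetic cued-attention EEG cohort generator with full
    ground truth supports calibration and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
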