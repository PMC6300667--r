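Package: pulvicor
Title: Pulvino-Cortical Functional Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the functional coupling between the human
    pulvinar and cortical areas from multi-subject fMRI. Implements a
    two-step Pearson correlation ("connectivity fingerprint") analysis that
    localizes each cortical area's coupling within the thalamus via
    leave-one-subject-out pseudo-group correlation profiles, together with
    the surrounding pipeline: resting-state time-series conditioning
    (despiking, band-pass filtering, detrending, nuisance regression,
    within-mask spatial smoothing), block-design GLMs with d-prime tuning
    indices, leave-one-out category ROI analysis, inter-subject correlation
    under movie scrambling for temporal-receptive-window mapping, and
    network-structure analyses (map similarity, classical MDS, Procrustes
    permutation tests, Newman spectral modularity clustering, Dice overlap,
    peak localization, and cortical-distance relationships). Includes a
    multi-subject synthetic data generator with planted networks,
    topographic gradients and ground-truth labels for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    vegan,
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
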