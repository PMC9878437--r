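Package: coilprint
Title: Head-Position SNR Artifacts in Infant Connectome Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how an infant's head position inside an
    inhomogeneous phased-array receive coil modulates regional temporal
    signal-to-noise (tSNR) and thereby inflates within-session connectome
    fingerprinting. Provides a synthetic-cohort generator (smooth coil
    sensitivity field, rigid-body head poses, SNR-coupled ROI BOLD
    timeseries), tSNR mapping with reslicing and soft-mean group averaging,
    head-pose based per-ROI SNR prediction, split-session Pearson
    connectomes with ROI quality control, Spearman representational
    similarity and identification ("fingerprinting"), and the edge-wise and
    stability regression models linking SNR to functional connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
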