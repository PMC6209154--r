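Package: eegstates
Title: Dynamic Brain Functional States from Multichannel EEG Phase Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of dynamic brain functional states from multichannel
    EEG-like recordings. Builds per-frequency-band phase-synchronization
    networks on a 20-channel 10-20 montage, partitions them into functional
    communities by modularity maximization with a Newman-Girvan null model
    and data-driven resolution selection, pools partitions into module
    allegiance matrices, and scores integration and recruitment of motor,
    cognitive and visual systems across practice sessions. Also computes
    behavioral and spectral features (completion time, NASA-TLX difficulty,
    tool-based performance scores, frontal alpha asymmetry, movement-related
    desynchronization, network strength and communication) and the
    correlation reports that relate network reconfiguration to motor-skill
    acquisition. A synthetic-data module generates recordings and feature
    tables with planted phase-coupled community structure and configurable
    effect sizes, so every stage of the pipeline can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
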