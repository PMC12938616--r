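Package: nfbloop
Title: Closed-Loop Real-Time fMRI Neurofeedback Simulation and Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and scores closed-loop real-time fMRI neurofeedback
    sessions in which participants regulate the BOLD signal of a sensorimotor
    region of interest toward cued target levels. Provides block-design
    schedule generation with BIDS-style event export, a synthetic cohort
    generator (hemodynamic forward model with AR(1) noise and drift,
    modality-dependent feedback tracking and within-session learning,
    right-skewed latency logs), per-TR feedback normalization and display
    mapping for continuous, categorical and no-feedback modalities, block
    success classification, a streaming localizer GLM with threshold-and-
    cluster ROI selection and display calibration, occupancy and
    distance-to-range performance metrics, exact paired Wilcoxon signed-rank
    and Friedman tests with Cohen's dz effect sizes, and latency quality
    control with heavy-tail outlier accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
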