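Package: microstatr
Title: Resting-State EEG Microstate Analysis with Verifiable Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Resting-state EEG microstate analysis: preprocessing with
    amplitude-based epoch rejection and common average referencing, global
    field power peak map extraction, topographic atomize-and-agglomerate
    hierarchical clustering (T-AAHC), canonical A-D template labeling,
    backfitting with short-segment rejection, temporal parameters (mean
    duration, occurrence, time coverage, transition probabilities), and
    case-control group statistics (ANCOVA with covariate adjustment and
    false discovery rate correction, Pearson correlations with Fisher-z
    confidence intervals). Includes a semi-Markov synthetic-EEG generator
    with exported ground truth for end-to-end validation, and BrainVision
    file input/output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
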