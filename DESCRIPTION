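Package: serpfold
Title: Co-Translational Chaperone Binding Prediction and Selective
    Ribosome Profiling Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts co-translational Trigger Factor and DnaK binding
    profiles from predicted protein structures using an unsatisfied-residue
    model of nascent-chain folding, and computes selective ribosome
    profiling (SeRP) enrichment statistics: sliding-window Agresti-Coull
    confidence intervals, per-gene engagement scores, binding onsets,
    metagene and domain-wise metagene summaries, dynamic-time-warping
    profile clustering, and normalized cross-correlation between model
    predictions and SeRP profiles. Includes a synthetic-data generator
    producing toy structures with planted domain architectures and
    two-replicate overdispersed footprint counts with known truth, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
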