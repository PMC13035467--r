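Package: screenflow
Title: Simulation and Inference for AI Integration into Double-Read Breast Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to evaluate how an AI reader can be integrated into a
    double-reading mammography screening programme. Provides an episode-level
    cohort schema with validation and CSV/TSV interchange, a calibrated
    synthetic cohort generator, a deterministic engine for seventeen AI
    reading workflow configurations (AI additional read, triage, triage
    negatives, and their combinations at multiple operating points),
    screening performance metrics with Wilson confidence intervals and a
    reader-workload ledger, paired percentile-bootstrap ratio confidence
    intervals with gated non-inferiority and superiority testing, and a
    Monte-Carlo power calculator for paired non-inferiority designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
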