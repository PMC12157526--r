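Package: tensorTRF
Title: Low-Rank Tensor Temporal Response Functions for Multichannel
    Neural Encoding Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits linear encoding models that predict multichannel neural
    time series (e.g. MEG) from sparse word-embedding event streams through
    a finite-impulse-response filter over post-word-onset delays. The filter
    is parameterized either densely (per-channel ridge regression with
    sequential cross-validation) or as a low-rank canonical polyadic (CP)
    tensor whose delay, embedding and channel factors are optimized jointly
    by Adam on a ridge-regularized squared-error loss. Includes
    noise-ceiling-normalized evaluation from repeated presentations,
    excess-predictability latency analysis, bootstrap and permutation
    significance tests, leave-one-out component influence, factor power and
    most-activating-context interpretation, low-level control
    residualization (log-mel spectrogram and sentence-event features), and
    a synthetic-data generator so the full workflow is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    data.table,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
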