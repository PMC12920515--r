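Package: envtrf
Title: Temporal Response Functions for Clean and Noise-Vocoded Speech EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sensor-level analysis of cortical tracking of the speech
    envelope under clean and degraded (noise-vocoded) listening
    conditions. Provides an N-channel noise vocoder, an auditory-filterbank
    broadband-envelope front end, EEG preprocessing (FIR band-pass,
    polyphase resampling, epoching, repetition averaging, pooled baseline
    normalization, alpha-power control), ridge-regression temporal response
    function (TRF) estimation with leave-one-out cross-validated lambda
    search, global-field-power component detection with pointwise paired
    t-tests and Benjamini-Hochberg FDR correction, stimulus-shuffling
    (derangement) permutation validation, and a synthetic multi-subject
    EEG generator with known ground-truth kernels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
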