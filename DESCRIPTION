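Package: ecstrf
Title: Efficient-Coding Models of Auditory Spectro-Temporal Receptive Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and solver for efficient-coding accounts of auditory
    receptive fields. Generates Gaussian stimulus ensembles with controlled
    spectral and temporal correlation structure, solves the
    information-versus-cost optimal gain allocation across decorrelated
    channels, assembles localized spectral filters, causal minimum-phase
    temporal filters and two-dimensional spectro-temporal receptive field
    (STRF) kernels, and quantifies how their modulation transfer functions
    adapt to stimulus intensity (signal-to-noise ratio) and correlation range.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
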