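Package: embedeeg
Title: Linking Contextual-Embedding Sentence Features to EEG Band Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes fourteen sentence-level features from contextual
    token embeddings (cumulative Euclidean, cosine, Manhattan and
    Chebyshev distances; unit-vector norms from two embedding sources;
    convex-hull geometry of PCA-projected tokens; cumulative masked
    language-model surprisal), turns event-marked multichannel EEG into
    per-epoch frequency-band power via Welch spectral estimation, and
    links the two with linear mixed models carrying crossed random
    intercepts for participants and runs.  Includes a synthetic-data
    generator with known ground truth for end-to-end parameter-recovery
    validation, plus readers for EDF recordings and tabular event,
    unit and feature files.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    lme4,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
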