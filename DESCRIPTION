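Package: ecglink
Title: Link-Constrained CNN-Transformer Classification of 12-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end arrhythmia classification of variable-length 12-lead
    electrocardiogram records. Implements difference-method outlier clipping and
    six-level bior2.6 wavelet denoising, fixed-window segmentation, a
    seven-layer convolutional feature extractor applied per window, a
    transformer encoder over the window sequence producing a fixed-width record
    embedding, and a must-link/cannot-link pairwise regularizer added to the
    cross-entropy training loss so that embeddings of same-class records become
    similar and embeddings of different-class records become dissimilar.
    Includes a class-conditional synthetic 12-lead ECG generator, evaluation
    diagnostics (per-class and macro F1, class-center embedding similarity),
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
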