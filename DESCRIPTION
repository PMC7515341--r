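Package: mtfse
Title: Multi-Band Time-Frequency Spectrum Entropy Indices for Short-Time HRV
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens for obstructive sleep apnea from 5-minute heart-rate-variability
    segments. Estimates the power spectrum of the RR-interval tachogram with a
    Burg-fitted autoregressive model, assembles a time-frequency spectrum image,
    splits it into the canonical VLF/LF/HF bands, and summarises each (sub-)image by
    its 2-D Shannon entropy, yielding an eight-index feature vector. Includes a
    seeded synthetic RR-interval generator with apnea-like cyclic modulation, an
    ectopic-beat median filter, cubic-spline resampling, Welch t-test screening, and
    a repeated, subsampled, stratified k-fold cross-validation harness with
    KNN/SVM/decision-tree adapters reporting accuracy, sensitivity and specificity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    class,
    e1071,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
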