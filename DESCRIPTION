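Package: ecgstream
Title: Streaming ECG Arrhythmia Detection with Micro-Batch Semantics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale toolkit for real-time cardiac arrhythmia detection
    from single-lead 360 Hz ECG. Signals are replayed as 5-second packets
    through a single-process micro-batch engine with exactly-once delivery:
    each batch is band-pass filtered (linear-phase FIR), R-peaks are detected
    with a Pan-Tompkins style online detector, beats are cut to a fixed
    200-sample window (69 samples before the R-peak, 130 after), reduced to
    25 wavelet approximation coefficients by repeated dyadic subband
    decomposition, and classified into normal, right-bundle-branch-block or
    atrial-fibrillation beats by a multiclass random forest. Includes a
    seeded synthetic ECG generator, MIT/BIH-dialect WFDB and CSV readers,
    a one-vs-rest multiclass metric suite, model persistence, checkpointed
    fault-tolerant streaming and a per-batch progress reporter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    randomForest,
    rpart,
    nnet,
    pROC,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
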