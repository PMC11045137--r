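Package: noterisk
Title: Magnitude-Aware Numerical Embeddings for Clinical-Note Outcome
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts binary surgical outcomes from free-text clinical notes
    with convolutional (TextCNN) and recurrent (TextLSTM) classifiers whose
    numeric tokens are embedded by magnitude rather than by surface form.
    Implements out-of-context number replacement (ROOC), a learned
    sigmoid-linear-log scaling embedding for lab values (ScaleNum), and its
    refinement by multi-head attention over the keyword context window
    (AttnToNum), together with a stratified split/calibration/AUC experiment
    harness, paired sign-flip permutation tests for model comparison, exact
    ngram-resolution SHAP attribution for max-pooled convolutional
    classifiers (SHAP-N), and a seeded generator of synthetic surgical
    consult notes with lab-value-driven outcomes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
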