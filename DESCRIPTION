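Package: audiotype
Title: Hearing Loss Type Classification from Pure-Tone Audiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying pure-tone audiometry results into normal
    hearing, conductive, mixed and sensorineural hearing loss. Provides
    readers and writers for tabular and XML representations of tonal
    audiometry records, validity screening of audiograms after Margolis and
    Saly, a deterministic air-bone-gap rule engine for diagnostic labelling,
    a seeded generator of rule-consistent synthetic audiograms, sequence
    encoding with four feature-scaling schemes and class-imbalance weights,
    a bidirectional LSTM sequence classifier with an LSTM-only variant and a
    gain-ratio decision-tree baseline, plus a full evaluation harness:
    stratified K-fold cross-validation, per-class and aggregate metrics,
    micro-averaged one-vs-rest ROC-AUC and McNemar's paired test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
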