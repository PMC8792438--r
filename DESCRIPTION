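Package: msmra
Title: Multi-Source Multi-Representation Adaptation for Cross-Domain EEG
    Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-subject and cross-session EEG emotion
    recognition under covariate shift. Implements differential-entropy
    band-feature extraction from multichannel EEG, two-partition
    multi-source domain grouping, a shared feature extractor feeding
    per-domain multi-representation branches aligned to an unlabeled
    target with a multi-kernel maximum mean discrepancy penalty,
    per-domain softmax classifiers, and a dynamically weighted joint
    training objective, together with a synthetic multi-domain generator
    for end-to-end testing without access to license-gated EEG corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
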