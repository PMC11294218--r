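Package: damgcn
Title: Dual-Attention Graph Convolutional Networks for EEG Emotion Decoding
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Decodes emotional state from multichannel EEG using differential
    entropy features on canonical frequency bands, a fixed electrode-distance
    graph convolutional network, and dual (electrode-channel and
    frequency-band) multi-head self-attention, trained with Adam and
    cross-entropy under ten-fold, leave-one-trial-out and
    leave-one-subject-out cross-validation.  Includes attention-based
    interpretability (band weight proportions, channel degree centrality),
    standard 32- and 62-channel montages, and a synthetic EEG generator that
    plants band- and channel-localized class structure so the full pipeline
    is testable without access to license-gated recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
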