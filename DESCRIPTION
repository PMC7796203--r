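Package: semgpe
Title: Multiscale Singular-Value Permutation Entropy and Deep Belief
    Networks for sEMG Gesture Recognition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for classifying hand gestures from multichannel surface
    electromyography (sEMG). Implements the discrete Stockwell transform
    for time-frequency analysis, multiscale singular-value decomposition of
    the time-frequency matrix with permutation-entropy feature reduction,
    and a deep belief network (stacked restricted Boltzmann machines with a
    softmax head) trained by contrastive-divergence pretraining and
    gradient fine-tuning. Includes a synthetic-signal generator that
    emulates class-dependent forearm muscle activity, a delimited-text
    signal format with dataset manifests, and an end-to-end pipeline with a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
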