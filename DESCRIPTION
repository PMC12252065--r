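Package: harspectrum
Title: Learning Paradigms Across the Supervision Spectrum for
    Wearable-Sensor Human Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements and compares six representation-learning paradigms
    for human activity recognition (HAR) from multichannel wearable-sensor
    streams: a supervised residual temporal convolutional network (TCN),
    an unsupervised residual autoencoder on handcrafted statistical
    features, weakly supervised Siamese metric learning from pairwise
    activity constraints (single- and multi-task with a person head),
    consistency-regularized self-supervision (temporal and feature-space
    neighborhood consistency), and a two-stage weakly self-supervised
    hybrid that pre-trains with consistency losses and fine-tunes with a
    small budget of pairwise constraints.  Includes a synthetic stream
    generator with per-activity stationary signatures and per-person
    nuisance variation, sliding-window segmentation, seven-statistic
    feature extraction, k-means cluster-to-label evaluation with
    Hungarian mapping, and a small command-line interface.  All networks
    are trained with an in-package reverse-mode gradient engine built on
    base R matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
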