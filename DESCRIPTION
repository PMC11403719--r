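Package: mstdflow
Title: Optic-Flow Simulation and Models of Self-Motion Encoding in Area MSTd
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates instantaneous optic-flow fields produced by combined
    three-dimensional translation and rotation of an observer through
    frontoparallel-plane and ground-plane scenes, transforms them into the
    activations of a population of speed- and direction-tuned model MT
    neurons, and fits a non-negative matrix factorization (NNMF) model of
    primate area MSTd to those activations.  Accuracy-optimized feedforward
    neural networks (convolutional and multilayer-perceptron variants, with
    optional non-negative weight constraints and L1 regularization) are
    provided for comparison, together with linear-regression decoding of
    self-motion from model populations and a suite of tuning-curve
    statistics: population-vector direction preferences, heading and
    rotation tuning indices, tuning widths, peak heading discriminability,
    axis-proximity tables, and population/lifetime sparseness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
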