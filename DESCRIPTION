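Package: cfnet
Title: Controlled Forgetting Networks for Unsupervised Lifelong Learning
    in Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-driven simulation of single-layer leaky integrate-and-fire
    spiking neural networks trained with a one-sided, Oja-stabilized
    spike-timing-dependent plasticity rule. A self-firing dopaminergic unit
    detects novel inputs, stimulates under-used neurons through trained
    dopaminergic weights and triggers one-shot re-learning, enabling
    unsupervised class-incremental (lifelong) learning without catastrophic
    forgetting. Includes Poisson rate encoding, an MNIST IDX reader/writer, a
    synthetic clustered-data generator, closed-form shot-noise membrane
    potential statistics with Monte-Carlo oracles, class-sequential training
    and evaluation protocols, non-dopaminergic and random-weight baselines,
    and a hyper-parameter sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
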