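Package: delaysnn
Title: Conduction-Delay Learning in Probabilistic Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and trains a single-post-synaptic-neuron spiking neural
    network that classifies spatio-temporal spike patterns by the timing of its
    output spike. Both the axonal conduction delay and the synaptic weight of
    every synapse are learned by a stochastic Expectation-Maximization rule
    whose windows mimic spike-timing-dependent plasticity. Two generative
    readouts are provided: a Multinoulli (softmax over time, exactly one output
    spike) model and a Bernoulli per-time-bin model with homeostatic intrinsic
    excitability. Includes latency encoders for feature vectors and images, a
    noisy toy-pattern generator, quantile decision boundaries for unsupervised
    classification, a weakly supervised teacher-spike mode, and experiment
    drivers that report classification accuracy over repeated trials.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
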