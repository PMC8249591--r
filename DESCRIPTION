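Package: periphnet
Title: Convolutional Encoder-Decoder Surrogates of Auditory Sensory-Cell and
    Synapse Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid computational-neuroscience framework that converts
    analytical models of auditory sensory cells and synapses (inner-hair-cell
    transduction, the three-store diffusion model of the auditory-nerve-fiber
    synapse, and the classical Hodgkin-Huxley squid axon) into differentiable
    convolutional encoder-decoder surrogate networks.  Provides calibrated
    acoustic stimulus generators, desk-scale analytical teacher models,
    receptive-field design rules for strided convolutions, dataset windowing
    and scaling conventions, an L1/Adam training loop with hand-rolled
    backpropagation, a six-metric electrophysiology-inspired evaluation suite
    (excitation patterns, AC/DC ratio, potential-level growth, firing rates,
    rate-level and synchrony-level curves), module merging across stages, and
    a backpropagation application that restores the output of a pathological
    model toward the normal-hearing response.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
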