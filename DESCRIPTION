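Package: eventprop
Title: Exact Event-Driven Gradients for Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation of recurrent leaky integrate-and-fire
    (LIF) networks with exact (closed-form) integration between spikes, and
    exact gradient computation through the discrete spike events via the
    adjoint method (the EventProp algorithm). The backward pass sweeps the
    spike event queue in reverse time, applying the adjoint jump conditions
    at each spike, and accumulates exact weight gradients. Includes two loss
    heads (first-spike-time cross-entropy and max-over-time voltage
    cross-entropy), latency encoders, a procedural Yin-Yang benchmark
    generator, an Adam training loop, and independent verification oracles
    (central finite differences, dense Euler integration, and the classic
    bouncing-ball hybrid system).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
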