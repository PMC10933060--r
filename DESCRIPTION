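Package: duplexneuron
Title: Activity-Gated Duplex Izhikevich Neuron Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulation of the Izhikevich spiking neuron and of its
    activity-gated "duplex" variant, which caches the expensive nonlinear
    right-hand-side terms of the model while the membrane potential is
    quasi-static and recomputes them only when the per-step voltage increment
    exceeds a threshold. Provides the reference forward-Euler stepper, the
    gated stepper, spike-train extraction, error metrics between unmodified
    and gated simulations (timing error, normalized root-mean-square
    deviation, computation-saving percentage, operation-cost speed-up), a
    bit-accurate fixed-point arithmetic layer emulating a Q16.14 hardware
    data path (shift-add constant multiplication and linear-mode CORDIC
    squaring) with an operation-count energy proxy, a 1,000-neuron randomly
    coupled excitatory/inhibitory network, and a three-layer feed-forward
    network trained with spike-timing-dependent plasticity to discriminate
    binary pixel patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
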