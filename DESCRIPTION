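Package: nav11dyn
Title: Nav1.1 Channel Gating Analysis and Cortical Neuron Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising voltage-gated sodium channel (Nav1.1)
    gating from whole-cell voltage-clamp recordings and for propagating the
    fitted gating parameters into a conductance-based cortical neuron model.
    Includes a synthetic voltage-clamp generator with known ground truth for
    the three standard pulse protocols (activation, steady-state fast
    inactivation, recovery from fast inactivation), Boltzmann and exponential
    curve fitting with temperature-sensitivity statistics, a Boltzmann
    reparameterisation of Hodgkin-Huxley sodium gating, and stimulus-sweep
    bifurcation analysis of depolarisation block and bistability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
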