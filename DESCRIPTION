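Package: signalmix
Title: Fully-Defined Signal Mixture Stimuli for Single-Neuron Encoding
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the fully-defined signal mixture paradigm in
    cellular electrophysiology. Synthesizes injectable current waveforms
    either as a systematic signal immersed in Ornstein-Uhlenbeck noise or
    as the summed postsynaptic currents of a large model presynaptic
    population with log-normally distributed amplitudes and balanced
    excitation and inhibition. Includes a calibrated leaky
    integrate-and-fire model neuron as a desk-scale stand-in for a
    patch-clamped cell, peri-stimulus time histogram construction, and
    parametric (binomial) and bootstrap decoders that quantify the
    probability of detecting individual excitatory or inhibitory inputs
    from population firing as a function of amplitude, integration
    window, population size and firing rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
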