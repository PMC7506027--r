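Package: eistim
Title: Stochastic Excitatory-Inhibitory Spiking Networks Under Neurostimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a stochastic Wilson-Cowan-type spiking
    network of excitatory and inhibitory neurons, its stochastic mean-field
    reduction with noise-smoothed transfer functions, saddle-node bifurcation
    and multistability detection, and a neurostimulation toolkit (pulse train,
    biphasic, sinusoidal and low-pass-filtered noise waveforms) with spike
    coherence, firing-rate and single-cell power-spectrum metrics. Supports
    studying how noisy or high-frequency periodic stimulation removes
    multistability and suppresses abrupt transitions into seizure-like
    oscillatory dynamics by preferentially recruiting inhibitory cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
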