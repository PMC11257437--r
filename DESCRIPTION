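Package: looplab
Title: Simulation Testbed for Closed-Loop Electrophysiology and Optophysiology Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Injects virtual experimental apparatus into spatial point-neuron
    network models: optic fibers and two-photon laser targets with
    Kubelka-Munk light propagation, four-state Markov and proportional opsin
    models with heterogeneous expression and multi-wavelength crosstalk,
    probabilistic extracellular spike detection with collision sampling,
    kernel- and synaptic-current-based local field potential proxies,
    two-photon calcium imaging with indicator dynamics, and a latency-aware
    I/O processor with exponential rate estimation and proportional-integral
    feedback control. Ships synthetic network fixtures and end-to-end demos
    so entire closed-loop experiments can be prototyped without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
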