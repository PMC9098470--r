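Package: bgdbs
Title: Subthalamo-Pallido-Thalamic Network Model of Parkinsonian Beta
    Oscillations and Deep Brain Stimulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley type) network model of the
    subthalamic nucleus (STN), external and internal globus pallidus (GPe,
    GPi) and thalamus, with healthy and Parkinsonian parameter presets,
    excitatory and inhibitory high-frequency deep brain stimulation (DBS)
    protocols, and cortico-thalamic sensorimotor drive. A fixed-step RK4
    integrator (compiled) runs seeded trial ensembles; an adaptive solver
    route (deSolve) provides an independent cross-check. The analysis layer
    implements sliding-window population firing rates, the Fano factor
    synchrony index, Welch power spectra with a beta-band (13-30 Hz)
    oscillation index, thalamic relay fidelity, burst statistics, and
    resting-state (excessive) thalamic activity, plus experiment runners
    that reproduce healthy/Parkinsonian characterization, DBS comparisons,
    amplitude sweeps and resting-state protocols from configuration.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
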