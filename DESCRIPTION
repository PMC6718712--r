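Package: okrsim
Title: Firing-Rate Simulation of Cerebellar Optokinetic-Reflex Gain Adaptation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic firing-rate model of the cerebellar circuit for
    optokinetic-reflex (OKR) gain adaptation. Three coupled synaptic-plasticity
    rate equations (parallel fiber-Purkinje cell, parallel fiber-molecular
    layer interneuron, mossy fiber-deep nuclei) are integrated through a
    daily train/rest session protocol, with a granular-layer transmission
    coefficient, a corticonuclear transfer coefficient, and an OKR gain
    read-out. A registry of lesion scenarios (granular-layer attenuation,
    blockade of train-induced or spontaneous plasticity, climbing-fiber
    blockade, interneuron lesions, corticonuclear disconnection) supports
    systematic in-silico lesion studies, with short-/long-term gain
    increment metrics, scenario comparison tables, a command-line interface
    and reference-curve fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
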