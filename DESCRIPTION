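Package: magbior
Title: Design and Simulation of Saturable-Core Electromagnet Arrays for
    Magnetic-Retention Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Magnetostatic modelling of planar arrays of saturable-core
    electromagnets used to retain magnetically immobilized enzymes and
    microorganisms in bench-scale bioreactors, together with the device
    sizing calculations (winding wire gauge under a mass budget, heater
    power, impeller Reynolds number and power) and discrete-time closed-loop
    simulators for the temperature, pH and stirring-speed control loops.
    Off-axis loop fields are evaluated exactly through complete elliptic
    integrals; ferromagnetic cores are modelled by a saturation-capped
    amplification of the bare-coil field with a magnetization/dipole route
    available for cross-checks. Field maps, axis profiles and control time
    series are exported as plain CSV with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
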