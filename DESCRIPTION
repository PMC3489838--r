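Package: trunkrelax
Title: Load-Relaxation Analysis of the Flexed Human Trunk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of in vivo trunk load-relaxation trials:
    seeded synthetic ramp-hold-ramp lumbar flexion exposures with a
    generalized-Maxwell (hereditary integral) ground truth, phase
    segmentation and windowed relaxation statistics (initial moment, moment
    drop, time to 90 percent drop), neutral-zone detection and hysteresis
    energies (E1, E2, dissipated energy and the RE viscoelastic-state ratio),
    bounded multi-start least-squares fitting of four viscoelastic
    relaxation models (standard linear solid, Prony series, Schapery power
    law, modified superposition), dimensionless parameter sensitivity
    coefficients, and exponential/linear trend fits of outcomes against
    lumbar flexion angle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
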