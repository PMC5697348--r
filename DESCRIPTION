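Package: ppGppSim
Title: Kinetic Simulation of ppGpp Dynamics and a ppGpp Biosensor in
    Batch-Grown E. coli
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic nine-ODE kinetic model of the stringent response
    (ppGpp) during batch growth of Escherichia coli, coupled to fatty-acid
    production by thioesterase-overexpressing lines and to a
    repressor-relay GFP biosensor of intracellular ppGpp. Provides a
    calibrated reference parameter set, a stiff-ODE scenario simulator with
    discontinuous events (nutrient upshift, ppGpp clamping) and growth-phase
    detection, biosensor metrics (steady-state dose-response, response time
    after nutrient upshift, peak fluorescence), producer-line experiments
    including Tes-activity sweeps and yield-based calibration, and a
    one-at-a-time parameter sensitivity scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
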