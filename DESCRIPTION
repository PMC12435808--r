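Package: perfusim
Title: Closed-Loop Temperature Management Simulation for Cardiopulmonary Bypass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates automated temperature management during cardiopulmonary
    bypass (CPB) as a closed loop between a finite-state setpoint controller
    and a lumped-compartment thermal model of the patient. Implements
    temperature-indexed perfusion policy tables (metabolic rate reduction,
    oxygen-delivery floors, pump-flow reduction, pH and CO2 strategies),
    safe-gradient and rate clamps on the heater-cooler unit setpoint,
    multi-site temperature sensing with noise, lag and dropout, median-based
    redundant sensor fusion, a debounced alarm engine with JSON-lines audit
    logging, and a seeded Monte-Carlo harness that measures gradient
    compliance of the controller under sensor dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
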