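Package: breathqa
Title: Quality Assurance of Respiratory Traces for 4DCT Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Individualized quality assurance of respiratory surrogate traces
    recorded during four-dimensional CT (4DCT) simulation. Parses Varian
    RPM/RGSC VXP breathing-trace exports (and a legacy two-column DAT dialect),
    independently detects breathing peaks and troughs, compares vendor-marked
    against detected breathing-rate and amplitude statistics, and flags scans
    that exceed statistical tolerances. Closed-form clinical impact models
    translate trace variability into phase-misbinning tumor displacement,
    gated-PTV geometric miss fractions, and amplitude-variability voluming
    errors with the extra internal-target-volume margin they require. A
    synthetic-trace generator with controllable period variability, level
    variability, drift, noise and mark-placement error provides a calibrated
    test substrate and cohort simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
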