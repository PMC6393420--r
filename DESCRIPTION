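Package: dtekit
Title: Device Thrombogenicity Emulation for Blood-Recirculating Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computational core for Device Thrombogenicity Emulation (DTE):
    reads Lagrangian platelet trajectories carrying viscous stress tensors,
    renders them into a von-Mises-type scalar stress, integrates stress
    accumulation (SA) along each trajectory, collapses SA ensembles into
    bootstrap-equalized probability-density "thrombogenic footprints", and
    compares device designs globally and per region of interest.  Includes an
    analytic annular Couette-Poiseuille pump surrogate with closed-form SA for
    end-to-end verification, pump operating-point arithmetic (rpm calibration,
    rotations, inlet mass flow), and platelet-activity-rate (PAR) statistics
    for recirculation-loop platelet activity state (PAS) assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
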