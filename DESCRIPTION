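Package: kneetwin
Title: Quasi-Static Twin of a Six-DOF Knee Joint Simulator with Virtual
    Ligaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transferring standardized tibiofemoral load cases between
    total knee replacement implant coordinate systems and into the Grood-Suntay
    joint coordinate convention, together with a nonlinear point-to-point
    virtual ligament apparatus (toe-region force law) and a quasi-static
    computational twin of a hybrid force/position controlled six
    degree-of-freedom joint simulator. Includes body-weight scaling of
    telemetric load data, rigid re-registration of kinematics and wrenches
    between implant frames, cycle periodisation for cyclic control,
    penalty-contact equilibrium solving, contact footprint estimation,
    flexion-binned comparison of soft-tissue variants, and deterministic
    synthetic generators for activity-of-daily-living load cases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
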