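Package: coroflow
Title: Reduced-Order Coronary Hemodynamics, Virtual Stenting and
    Non-Invasive Fractional Flow Reserve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state simulation of blood flow and pressure in coronary
    artery trees represented as centerlines with lumen-radius profiles.
    Computes a non-invasive fractional flow reserve (FFR) from patient
    blood pressure and left-ventricular mass via resistance outlet
    boundary conditions calibrated to the hyperemic inflow, deploys
    virtual stents on the centerline geometry to predict the hemodynamic
    effect of percutaneous coronary intervention, sizes stents
    automatically from the lumen-area curve, and provides the validation
    statistics used to compare simulated against invasive FFR (Pearson
    correlation, Bland-Altman agreement, diagnostic accuracy at the 0.80
    ischemia threshold, intraclass correlation and coefficient of
    variation). Includes a seeded generator of physiologically plausible
    synthetic coronary anatomies and validation cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
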