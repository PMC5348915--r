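Package: avfsim
Title: Patient-Specific Hemodynamic Prediction of Arteriovenous Fistula
    Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter (0D, hydraulic-electric analogy) model of the
    adult arm circulation for pre-operative planning of arteriovenous
    fistulae (AVF) for hemodialysis access. A generic RLC vascular network
    is personalized from demographics, clinical covariates and Doppler
    ultrasound measurements; a nonlinear anastomosis element represents the
    surgical connection; and a wall-shear-stress homeostasis rule evolves
    vessel radii from surgery to 40 days, predicting blood flow volume and
    diameters over the maturation period. Includes patient-form I/O,
    prediction reports, a synthetic-cohort generator and method-agreement
    statistics (linear regression, Bland-Altman) for cohort validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
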