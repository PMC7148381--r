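Package: protonRBE
Title: Inter-Patient Variable Proton RBE Analysis for Cranio-Spinal Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying inter-patient variation in the relative
    biological effectiveness (RBE) of proton cranio-spinal irradiation (CSI).
    Generates seeded synthetic patient cohorts (voxelized physical dose,
    dose-averaged LET and organ masks emulating a two-phase CSI plan with a
    posterior-fossa boost), evaluates constant and variable linear-quadratic
    RBE models per fraction, accumulates RBE-weighted dose over treatment
    phases, and computes organ-level (dose-weighted mean RBE, RBE of the
    near-maximum dose D2%) and population-level (cohort medians, ranges,
    population-based RBE-weighted dose, (alpha/beta)x confidence-interval
    sweeps) statistics, with NIfTI and CSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    RNifti,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
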