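Package: oculoflow
Title: Axisymmetric Porous-Media Model of Aqueous Outflow from the Human Eye
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady Darcy flow through the tissues of the human eye with
    pressure-dependent exponential outflow boundary conditions, solved on an
    axisymmetric finite-element mesh. Includes a closed-form lumped (0D)
    outflow model, geometry construction and structured meshing of the eye
    half-section, a Picard-iterated nonlinear Robin solver, postprocessing of
    translaminar pressure gradients, flow partitions, lamina cribrosa
    velocities and axonal-transport factors of safety, and a library of
    clinical scenarios (posture, nocturnal, normal-tension glaucoma,
    silicone-oil tamponade, Schwartz-Matsuo syndrome) with calibration
    workflows.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
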