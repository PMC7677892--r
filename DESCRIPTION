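Package: cardiomech
Title: Ventricular Electromechanics with Pericardial Robin Boundary Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale simulator of ventricular systolic motion on an
    idealized truncated-ellipsoid biventricular geometry. Implements
    rule-based myofiber generation, anisotropic eikonal activation,
    transversely isotropic Guccione passive mechanics with a volumetric
    penalty, a phenomenological active-tension transient, Windkessel-coupled
    pressure-volume phases, and spatially varying normal-spring (Robin)
    pericardial boundary conditions whose stiffness scaling is derived from
    an epicardial normal-displacement profile. Includes a synthetic
    target-motion generator, motion/hemodynamic metrics (atrioventricular
    plane displacement, apex displacement, ejection fraction), and paired
    with/without-pericardium experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
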