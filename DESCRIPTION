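Package: dpitrack
Title: Lagrangian Microparticle Transport, Adhesion and Detachment in
    Dry Powder Inhaler Geometries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-phase Lagrangian simulation of respirable microparticles
    (0.5-5 um) inside an idealized dry-powder-inhaler geometry. Implements
    van der Waals adhesion, the Dahneke/Brach-Dunn capture-velocity sticking
    criterion, coefficient-of-restitution bounce, and rolling/sliding
    detachment of deposited particles under near-wall shear, including the
    critical wall shear velocities for resuspension. Steady analytic surrogate
    flow fields (Poiseuille, chamber swirl, grid-jet composite) or gridded
    velocity fields (CSV / legacy VTK) drive one-way coupled particle
    tracking with a compiled integrator. Includes a normal/tangential
    restitution-coefficient sweep, particle-count independence checks,
    region-wise deposition reports, and per-particle adhesion diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
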