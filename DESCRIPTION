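Package: pahemo
Title: Reduced-Order Pulmonary Artery Hemodynamics Before and After
    Percutaneous Pulmonary Valve Implantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study pulmonary artery (PA) hemodynamics around
    percutaneous pulmonary valve implantation (PPVI) at desk scale.
    Generates synthetic bifurcating PA trees, pulsatile main-PA inflow
    waveforms with a controllable regurgitant fraction, and patient
    cohorts; constructs and calibrates three-element Windkessel (RCR)
    outlet boundary conditions with Murray's-law resistance distribution
    (exponent 2.3); solves the resulting lumped-parameter pulsatile
    network over repeated cardiac cycles; reconstructs analytic
    Womersley/Poiseuille in-segment velocity profiles; and computes the
    standard hemodynamic indices (Reynolds number, Womersley number,
    cross-sectional vorticity, energy dissipation, regurgitation
    fraction, forward/backward flow volumes and velocities). A
    statistics layer provides exact and normal-approximation Wilcoxon
    signed-rank and rank-sum tests and univariable-screened
    multivariable linear regression. Ships a per-patient index table
    fixture for summary reproduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
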