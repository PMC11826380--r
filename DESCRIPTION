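Package: porocirc
Title: Multiscale Coupling of Quasi-Static Poroelasticity with Lumped Hydraulic Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tissue perfusion by coupling a quasi-static Biot
    poroelastic model of a deformable porous medium (3D box or reduced 1D
    column) to a lumped-parameter RCL hydraulic circuit through a resistive
    and capacitive connection. Two interface-condition variants are provided,
    pointwise pressure continuity (PPC) and integral pressure continuity
    (IPC), discretized with Backward Euler in time and conforming finite
    elements in space. Time integration uses an energy-stable operator
    splitting that is unconditionally stable in the time step, alongside a
    partitioned pressure-flow (PQP) fixed-point iteration whose conditional
    convergence can be diagnosed. Includes a full energy and dissipation
    audit, exact matrix-exponential circuit solutions for verification,
    steady-state oracles, configuration parsing, and CSV/VTK output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
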