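Package: tricellfem
Title: Triphasic Finite-Element Simulation of Cardiomyocyte
    Excitation-Contraction Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Finite-element simulator of a cardiac ventricular myocyte
    segment based on triphasic mixture theory: a cytoskeletal solid phase,
    a cytosolic fluid phase and an ionic phase are solved together, coupling
    quasi-static poroelastic deformation, Darcy fluid motion under pressure,
    osmotic and electrical driving forces, and electroneutral
    convection-diffusion-electromigration of nine solutes.  Sarcolemmal
    electrophysiology uses a zero-thickness capacitance approximation with
    dual intra/extracellular potentials, a reduced six-current ionic model
    with distinct surface and t-tubular channel densities, and simplified
    triphasic truss elements for the t-tubule network (pressure-driven lumen
    flow, compliant dilation, restricted diffusion).  Reduced subcellular
    reactions supply calcium-induced calcium release, SERCA uptake,
    mitochondrial exchange and active tension.  Includes a synthetic
    subcellular mesh generator, multirate operator-split time stepping,
    twitch/voltage-clamp/solution-switch protocols, figure-style analyses
    (flux-term decomposition, release-delay versus distance, t-tubular
    potential profiles) and VTK/CSV exporters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
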