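Package: photoecmo
Title: Coupled Light-Flow-Heat Simulation of a Phototherapy Membrane Oxygenator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric simulator for a phototherapy extracorporeal membrane
    oxygenator (photo-ECMO) whose thin blood chamber is irradiated by external
    red LEDs to photodissociate carbon monoxide from hemoglobin. Provides a
    filleted-square device geometry model with priming-volume accounting,
    Monte Carlo photon transport into blood with cylindrical kernel revolution
    and LED-array superposition, a steady non-Newtonian (Carreau) finite-volume
    flow solver for the thin chamber, Lagrangian particle residence-time
    tracing, and a transient/steady convection-diffusion thermal solver with
    conjugate plexiglass conduction and natural-convection exterior cooling.
    Includes analytic verification fixtures (plane Poiseuille, Beer-Lambert
    slab, heated slab) and a pipeline that sweeps geometries and flow rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
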