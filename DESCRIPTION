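Package: stirredtank
Title: Gas-Liquid Stirred Bioreactor Simulation with Lagrangian Bubbles
    and Fermentation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator of gas-liquid stirred-tank bioreactors.
    Tracks sparged gas bubbles as discrete Lagrangian parcels (Schiller-Naumann
    drag, added mass, buoyancy, velocity Verlet integration), models per-bubble
    interphase mass transfer with a penetration-theory mass transfer
    coefficient, and couples the resulting dissolved-gas balances to reaction
    kinetics: constant-rate consumption/production pairs and Contois-type
    fermentation (biomass, product, substrate, dissolved oxygen). Provides
    analytic steady-state predictors, volumetric mass transfer coefficient
    (kLa) estimation by nonlinear regression of gassing-in curves, full
    molar-flux ledgers (sparge injection, free-surface removal, gas-liquid
    transfer, reaction), synthetic stirred-tank flow and energy-dissipation
    fields, and a coarse explicit advection-diffusion-reaction grid for
    spatially resolved dissolved-gas fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
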