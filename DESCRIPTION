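Package: rhizoflux
Title: Compartmental Simulation of Passive Ion and Water Transport in Plant Roots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A compartmental model of the coupled, passive transport of ions
    and water through a cylindrical plant root with radially distinct tissue
    layers (epidermis, cortex, endodermis, pericycle, xylem) and axially
    distinct developmental zones (elongation zone, differentiation zone).
    Water crosses membrane interfaces by Kedem-Katchalsky non-equilibrium
    thermodynamics with van't Hoff osmotic pressure, flows along the mature
    xylem by Darcy's law, and ions move by the extended Nernst-Planck flux
    (diffusion, electromigration, convection). Hydraulic pressure and electric
    potential are quasi-static fields re-solved at every evaluation of the
    stiff ordinary differential equation system. Apoplastic barriers
    (Casparian strip, suberin lamellae, passage cells) and xylem maturation
    are expressed as interface-parameter rules. Includes named experiment
    scenarios (barrier comparisons, transpiration sweeps, developmental
    offsets, transient ion addition), steady-state detection, summary
    statistics, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    methods,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
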