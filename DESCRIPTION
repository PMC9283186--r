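Package: scaffoldrom
Title: Parametric Reduced-Order Modelling of Calcium Transport in Bone
    Scaffold Pore Networks
Version: 0.1.0
Authors@R:
    person("scaffoldrom", "developers", email = "scaffoldrom@example.org",
           role = c("aut", "cre"))
Description: Steady nonlinear advection-diffusion finite-element modelling of
    calcium ion transport through the interstitial-fluid domain of microporous
    bone scaffolds, with Robin ion-release boundaries and a concentration-
    dependent Stokes-Einstein diffusivity. Includes voxel-based generators for
    synthetic foamed and 3D-printed scaffold pore geometries, a potential-flow
    velocity basis parametrized by inflow direction, proper orthogonal
    decomposition (POD) reduced-order solvers in standard, local, quadratic
    and local-quadratic variants, and a high-concentration volume-ratio
    quantity of interest for parametric sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    optparse,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
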