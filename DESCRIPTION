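Package: portalflow
Title: Reduced-Order Hemodynamic Modelling of Transjugular Intrahepatic
    Portosystemic Shunts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Patient-specific reduced-order (0D) simulation of the portal
    venous system after transjugular intrahepatic portosystemic shunt (TIPS)
    placement. Derives inlet flows and outlet resistances from routine
    clinical measurements (Murray's-law flow partitioning, postoperative
    flow doubling, resistance closure against a population portal pressure),
    builds parametric vessel networks for three shunt positions and three
    geometric simplification strategies, solves the nonlinear hydraulic
    network (Darcy-Weisbach/Blasius transitional losses, minor losses,
    Bernoulli static-pressure accounting) for nodal pressures and flows, and
    reports clinical comparison metrics: portal pressure gradient, shunt
    velocity, wall-shear-stress classification and relative errors between
    simplification strategies. Includes a seedable generator of
    physiologically shaped synthetic patient records for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
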