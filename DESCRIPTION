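Package: fsgr
Title: Fluid-Solid-Growth Simulation of Aneurysm Enlargement and Stabilization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale fluid-solid-growth (FSG) framework for vascular
    mechanobiology. Models the arterial wall as a two-layer fiber-reinforced
    hyperelastic composite in which collagen fibers carry a triangular
    distribution of recruitment stretches, computes pulsatile wall-shear-stress
    metrics (notably the wall shear stress aspect ratio, WSSAR), and evolves
    the wall through flow-driven growth and remodelling laws, namely mass
    degradation, recruitment-stretch remodelling, collagen mass growth, and
    adaptation of the homeostatic attachment-stretch distribution.
    Quasi-static equilibrium of an idealized axisymmetric vessel-plus-sac
    geometry is solved with a pointwise membrane (stress-resultant)
    formulation, and a reduced-order hemodynamic surrogate supplies wall shear
    stress with geometric feedback, so that homeostasis, enlargement and
    restabilization of an aneurysm sac can be simulated end to end on a single
    workstation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
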