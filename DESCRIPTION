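Package: axonmem
Title: Coarse-Grained Simulation of the Axon Plasma Membrane and Its Skeleton
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Particle-based coarse-grained molecular dynamics of the axon plasma
    membrane: a periodic actin/spectrin membrane skeleton (actin rings joined by
    spectrin tetramers), a two-leaflet implicit-solvent lipid bilayer with
    orientation-dependent pair potentials, transmembrane and monotopic membrane
    proteins, and the anchoring complexes that tether the bilayer to the skeleton.
    Includes Beeman time integration with constrained rotational degrees of
    freedom under a Nose-Hoover thermostat, cell-list neighbour search,
    builders for chains, rings, flat bilayer patches and reduced axon cylinders,
    and trajectory analysis: cylindrical unwrapping, directional mean squared
    displacements, and fitting of normal, confined, confined-hop and anomalous
    diffusion models with residual-norm model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
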