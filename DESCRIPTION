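Package: landingmech
Title: Multiscale Landing Biomechanics of the Knee
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale multiscale pipeline linking collagen-fibril
    mechanics to drop-landing loads on the knee. Provides a coarse-grained
    bead-spring molecular-dynamics model of collagen fibrils with breakable
    bonds, fibril-reinforced hyperelastic articular cartilage with
    depth-dependent composition and energy-limiter softening, a hierarchical
    hyper-elastoplastic ligament/tendon model with pre-strain, a transversely
    isotropic meniscus law, nonlinear landing-height regression models for
    lower-limb kinematics and kinetics, static optimization of muscle forces
    by minimizing the sum of cubed muscle stresses, and an elastic-foundation
    knee surrogate that searches for the critical landing height at which
    cartilage damage initiates. All inputs are generated synthetically, so
    every analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
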