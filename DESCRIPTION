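Package: efgm
Title: Element-Free Galerkin Simulation of Myocardial Electrical Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A meshfree simulator of electrical activation in cardiac tissue.
    The monodomain reaction-diffusion equation is discretized with the
    element-free Galerkin method: transmembrane potential is approximated by
    moving-least-squares (MLS) shape functions built over a cloud of
    unstructured sample nodes, and the Galerkin weak form is integrated on a
    regular background mesh with Gauss quadrature. Anisotropic conduction is
    modelled through per-point diffusion tensors rotated into nodal fiber
    orientations. Two membrane models are included (a cubic polynomial ionic
    current with a closed-form conduction velocity, and a modified
    FitzHugh-Nagumo model), together with finite-difference and linear
    finite-element baselines and scripted verification experiments: 2D heat
    conduction convergence, 1D cable conduction-velocity error, 3D anisotropic
    plane waves, and activation of an idealized ventricular shell.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
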