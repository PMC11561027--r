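Package: avtumor
Title: Stochastic Lattice and Mean-Field Simulation of Avascular Tumor Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analyzing the growth and morphology of
    avascular tumors in two dimensions. Implements a stochastic lattice model in
    which pressure-driven cell migration follows Darcy's law (continuous-time
    Markov chain simulation with quasi-stationary pressure and oxygen fields),
    the corresponding deterministic mean-field free-boundary model with a
    Young-Laplace surface-tension condition at the rim, the radially symmetric
    reduction of that model (closed-form oxygen profile, zonation relations,
    volume dynamics, stationary states and their eigenvalue), and the
    linear-stability dispersion relation for cosine perturbations of the tumor
    boundary, including the Saffman-Taylor, inner-region-perturbation and
    surface-tension contributions. Morphology utilities quantify roundness,
    regional volumes, boundary Fourier modes and mode growth rates, allowing
    direct comparison of stochastic simulations with the analytical predictions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    stats,
    grDevices,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png
Config/testthat/edition: 3
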