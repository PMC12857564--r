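Package: gfnamd
Title: Gradient-Free Machine-Learned Nonadiabatic Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for surface-hopping nonadiabatic molecular dynamics driven by
    differentiable multi-state, multi-fidelity surrogate potentials trained on
    electronic energies alone, with forces obtained by analytic differentiation of
    the fitted model. Ships analytic diabatic model potentials (linear crossing,
    avoided crossing, three-state linear vibronic coupling) as reference electronic
    structure, Wigner sampling of initial conditions, velocity-Verlet propagation
    with Landau-Zener-Belyaev-Lebedev hopping, ensemble statistics (binomial
    confidence intervals, bootstrap errors, exponential and delayed-exponential
    timescale fits, quantum yields, hop-geometry tables, branching ratios), and
    penalty-function optimization of minimum-energy conical intersections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
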