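Package: ramaibi
Title: Iterative Boltzmann Inversion of Backbone Dihedral Potentials
    Against Ramachandran Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for parametrizing separable Fourier-series backbone
    dihedral potentials by iterative Boltzmann inversion against target
    Ramachandran distributions, and for scoring conformational ensembles of
    short peptides against spectroscopic observables.  Provides binned
    (phi, psi) probability distributions with Hellinger-distance and
    mesostate-population analysis, a wrapped-Gaussian superposition model of
    residue ensembles, Karplus-equation J-coupling and coupled-oscillator
    vibrational circular dichroism forward models with reduced chi-squared
    scoring, exact-Boltzmann and Metropolis samplers, text-format readers and
    writers (gmx-rama xvg, GROMACS dihedraltypes fragments, grid matrices,
    parameter tables), synthetic fixture generators with known ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
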