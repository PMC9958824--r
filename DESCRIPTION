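Package: isoswell
Title: Isotonic Two-Compartment Model of Neuronal Swelling by
    Co-Transport of Salt and Water
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Equilibrium-thermodynamic model of cytotoxic neuronal
    swelling in brain tissue. Two compartments (interstitial space and
    neurons) exchange monovalent ions and water through co-transporters
    at fixed solvent-to-solute ratios, so that every intermediate state
    of the swelling path is isotonic and electro-neutral. The package
    solves the state of full equilibrium and the per-species transport
    concentrations from a physiological ion table, computes Donnan
    equilibria at arbitrary intermediate extracellular volume fractions,
    evaluates the hyperbolic concentration-volume laws and Nernst
    potentials along the isotonic path, and decomposes the released
    Gibbs energy into work of mixing and osmotic work (including the
    isochoric complete-mixing and Donnan reference scenarios). Includes
    conservation audits, report writers for the model's tables and
    figure data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
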