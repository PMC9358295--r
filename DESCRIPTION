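Package: aquahumor
Title: Compartmental Model of Aqueous Humor Production by the Ciliary Epithelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state compartmental model of water and solute transport
    across the ciliary epithelium of the eye. Given stromal solute
    concentrations and the channel, transporter and pump complement of the
    stromal and posterior-chamber membranes, the package solves the coupled
    nonlinear balance equations for intracellular and posterior-chamber
    composition, electric potentials and the osmotic water (aqueous humor)
    production rate. Includes a time-dependent relaxation solver for
    stability checks, in-silico experiments (carbonic anhydrase inhibition,
    pump knockdown, parameter scaling), and extended Fourier Amplitude
    Sensitivity Test (eFAST) global sensitivity analysis of the channel
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
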