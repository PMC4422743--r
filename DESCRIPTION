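Package: saxsens
Title: Ensemble Deconvolution of Protein (Un)folding from Solution X-Ray Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects weighted sub-ensembles of protein conformers whose
    ensemble-averaged X-ray scattering reproduces an experimental S/WAXS
    curve, using a genetic algorithm over fixed-capacity multisets of
    conformer indices. Includes a Debye-equation scattering calculator with
    excluded-volume solvent correction, GROMOS-style (Daura) RMSD
    clustering of conformer pools, classification of fitted ensemble weight
    into native/intermediate/unfolded groups by radius of gyration, and
    cross-validation of ensembles against NMR observables (residual
    dipolar coupling Q factors with sliding-window maps, power-averaged
    NOE distance-restraint violations). A synthetic-data module generates
    conformer pools with controlled unfolding, mixture scattering
    experiments, RDC sets from known alignment tensors, and NOE-style
    restraint sets, so every stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
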