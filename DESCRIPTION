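Package: ifmech
Title: Coarse-Grained Mechanics of Keratin and Vimentin Intermediate
    Filaments Under Cyclic Loading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo simulators and analysis tools for stretch-relax
    cycles of single intermediate filaments probed by optical tweezers.
    Keratin filaments are modeled as a lattice of dimers whose lateral
    interactions rupture under load and rebind one axial period further
    (subunit sliding), producing plastic elongation at constant stiffness;
    vimentin filaments are modeled through force-driven alpha-helix
    unfolding into a persistent soft random-coil state, producing
    softening at constant length.  The package implements the complete
    force-strain cycle analysis used for such experiments: reference
    length at 5 pN, effective-length extrapolation from a 100-150 pN
    window fit, force- and strain-window stiffnesses, corrected strain,
    hysteresis energies (relative and per length in kBT/um), cohort
    summaries, and cross-filament elongation regressions, together with a
    synthetic optical-tweezers trace generator with injected ground truth
    for end-to-end pipeline validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    optparse,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
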