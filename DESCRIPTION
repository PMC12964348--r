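Package: sanstools
Title: Contrast Matching and Form-Factor Model Fitting for Small-Angle
    Neutron Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for small-angle neutron scattering (SANS) studies of
    biomolecules and their insoluble partners. Computes neutron
    scattering-length densities and contrast match points for H2O/D2O
    solvent series, including the integrated-intensity quadratic-minimum
    estimator used with contrast-variation measurements. Evaluates the
    scattering models used for semiflexible polysaccharide nanofibers and
    hierarchical protein-fiber aggregates: a wormlike-chain (flexible
    cylinder) form factor with excluded-volume corrections plus a power-law
    term, the multi-level Beaucage unified scattering model, and a
    random-walk chain of ellipsoids. Provides weighted nonlinear
    least-squares fitting with the constraints used in fiber work (fixed
    contour length, radius-of-gyration bound at pi/q_min, two-stage
    unified-model fitting), a reader/writer for columnar reduced SAS data,
    a synthetic-data generator for instrument-like curves and
    contrast-variation series, and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
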