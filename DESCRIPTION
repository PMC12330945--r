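Package: meltshift
Title: Thermal Proteome Profiling and CETSA Melting-Curve Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits the three-parameter equilibrium unfolding (sigmoid with
    plateau) model to protein thermal denaturation curves, extracts melting
    points (Tm), computes and ranks ligand-induced melting-point shifts
    (delta Tm) across a proteome, classifies stabilized and destabilized
    binding-target candidates, applies a two-fold differential-expression
    rule, and analyzes CETSA immunoblot densitometry series into apparent
    Tm50 values. Includes a synthetic thermal-proteome generator with known
    ground truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    tools,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
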