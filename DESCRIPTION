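Package: apoptosense
Title: Systems-Level Apoptosis Sensitivity Analysis for Medulloblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pathway-informed analysis of intrinsic-apoptosis protein
    expression to classify chemosensitivity in medulloblastoma. Implements
    functional-group construction from relative protein quantification,
    z-score normalisation, principal component analysis with Kaiser-criterion
    retention and linear discriminant classification of high versus reduced
    cisplatin sensitivity; interquartile mapping of patient cohort mRNA onto
    the cell-line protein scale with projection into the fitted component
    space; equilibrium and reduced-ODE surrogates of BCL-2 family
    competitive binding (stress-dose score with in-silico BH3-mimetic
    administration) and of apoptosome-driven caspase execution; and
    pharmacology utilities (four-parameter logistic IC50 fitting, Webb
    fractional-product synergy, JC-1 plate BH3-profiling normalisation and
    dynamic delta-priming). A synthetic-data module generates every input
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
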