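Package: peranova
Title: Partitioned-Error Repeated-Measures ANOVA and ANCOVA for
    Mass-Univariate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Symbolic derivation of expected mean squares for mixed-measures
    factorial designs, automatic error-term selection, multi-model planning
    with within-subject averaging, Type III estimable contrasts derived from
    design-matrix rows, partitioned-error model fitting for long-format
    tables and image stacks, stratum-matched continuous covariates, and
    classical sphericity assessment with Greenhouse-Geisser and Huynh-Feldt
    degrees-of-freedom corrections. Implements the multi-model general linear
    model workflow used for group-level repeated measurements in
    mass-univariate neuroimaging analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
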