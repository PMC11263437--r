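Package: phenosel
Title: Phenomic Selection with Near-Infrared Spectra in Multi-Environment
    Trials
Version: 0.1.0
Authors@R:
    person("phenosel", "developers", email = "phenosel@example.org",
           role = c("aut", "cre"))
Description: Tools for phenomic selection in plant breeding programs:
    simulation of multi-environment field trials (partially replicated and
    alpha-lattice designs) with near-infrared reflectance spectra, REML
    linear mixed models for genotype adjusted means (BLUEs), variance
    components and Cullis heritability, Savitzky-Golay spectral filtering
    with grid-search parameter tuning, eight feature-engineering scenarios,
    ridge-regression BLUP and partial least squares regression predictors,
    repeated cross-validated prediction ability for three breeding
    scenarios, and discriminant analysis of principal components for
    spectral structure diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
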