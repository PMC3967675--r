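Package: conjspec
Title: Monte Carlo Reflectance Modeling of the Palpebral Conjunctiva for
    Noninvasive Hemoglobin Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modeling of palpebral-conjunctiva
    reflectance spectra for noninvasive hemoglobin determination. Implements
    a seven-layer optical model of the human lower eyelid (conjunctival
    epithelium through stratum corneum), wavelength-resolved chromophore
    absorption (oxy- and deoxyhemoglobin, water, melanin, baseline tissue),
    a photon-packet Monte Carlo transport engine with Henyey-Greenstein
    scattering and Fresnel boundary handling, sensitivity analysis of the
    simulated spectra, and an iterative sum-of-squared-residuals inversion
    that recovers hemoglobin concentration and blood oxygenation from
    measured spectra, with leave-one-out cross-validation and clinical
    agreement statistics. Includes a synthetic-cohort generator so the full
    pipeline can be exercised without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
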