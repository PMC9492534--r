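Package: twinace
Title: Twin-Based ACE Variance Decomposition of Longitudinal Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classical twin-design analysis of longitudinal body mass index
    and height: full-information maximum-likelihood estimation of univariate
    and bivariate Cholesky ACE/AE models with zygosity-specific means and a
    sex-limitation structure for opposite-sex pairs, decomposition of
    age-to-age phenotypic correlations into additive genetic, shared
    environmental and unique environmental correlations, profile-likelihood
    and Wald confidence intervals, and assembly of per-sex age-by-age
    correlation matrices across childhood and adolescence. Includes a seeded
    synthetic twin-cohort generator calibrated to published descriptive
    growth moments, residualization-based preprocessing, closed-form
    method-of-moments oracles, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
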