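Package: piur
Title: Profile Inter-Unit Reliability for Health Care Provider Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reliability assessment of provider-level quality measures with
    emphasis on outlier identification. Implements the inter-unit reliability
    (IUR) via one-way ANOVA variance components with the effective provider
    size correction for unbalanced panels, fixed-effects (FE), random-effects
    (RE), fixed-effects-with-random-intercept (FERE) and empirical-null (EN)
    Z-score profiling, closed-form split-half reflagging calibration curves
    based on bivariate normal orthant probabilities, the profile inter-unit
    reliability (PIUR) obtained by inverting those curves at an empirical
    split-half reflagging rate, a contamination-model simulator, and an
    extension to standardized-ratio count measures (observed/expected) under
    a Poisson approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    mvtnorm,
    MASS,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
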