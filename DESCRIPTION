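Package: tairisk
Title: Tissue-Deformation Metrics and Risk Curves for Traumatic Axonal Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing traumatic axonal injury (TAI) risk criteria
    from tissue deformation. Implements a fiber/matrix Holzapfel-Gasser-Ogden
    hyper-viscoelastic material model with quasilinear viscoelasticity and
    DTI-informed fiber dispersion, discretization of tractography streamlines
    into 1-mm cable elements with fractional-anisotropy grouping, twelve
    strain and strain-rate injury metrics (95th-percentile and cumulative
    fraction metrics), injury risk curves by binary logistic regression,
    censored Weibull survival fits and ROC analysis, repeated stratified
    k-fold cross-validation with fraction-metric cutoff optimization, a
    marker-triad strain validation procedure with two-sample
    Kolmogorov-Smirnov comparison, and a synthetic-data generator that
    emulates a rotational-injury animal cohort so the whole chain is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
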