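Package: trioiv
Title: Offspring-as-Instrument Analysis of Body Mass Index and Long-Term Sick Leave
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrumental-variable analysis of the effect of body mass index
    (BMI) on the hazard of long-term sick leave, using offspring BMI as an
    instrument for parental BMI. Provides stratified and LMS (Box-Cox)
    BMI z-scoring, left-truncated Cox proportional-hazards estimation on the
    age time axis with restricted-cubic-spline-by-survey adjustment, the
    single-instrument ratio (Wald) estimator with Taylor-series (delta-method)
    confidence intervals, weak-instrument diagnostics (partial R-squared and
    partial F), bias component tables contrasting conventional and
    instrumental-variable covariate associations, a proportional-hazards
    split-follow-up check, and a synthetic family-trio generator with known
    causal structure (shared confounding, reverse causation through latent
    illness) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
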