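Package: kidrisk
Title: Criterion Validation Toolkit for Pediatric Obesity-Risk Screeners
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores picture-based pediatric obesity-risk questionnaires and
    tests their criterion validity against objective child measures. Provides
    instrument scoring and dichotomization from a validated codebook,
    LMS-based BMI-for-age z-scores and percentiles with CDC-style weight
    categories and waist-to-height ratios, immunoassay quality control
    (replicate selection by coefficient of variation, internal-control plate
    normalization, Tukey-fence outlier screening), derived biomarkers
    (Friedewald LDL-C, non-HDL-C, HOMA-IR and lipid/adipokine ratios),
    composite metabolic, lipid and anti-inflammatory z-score indices,
    anthropometry-driven item reduction, nonparametric two-group validation
    reports, and a synthetic parent/child dyad cohort generator with a latent
    adiposity factor for end-to-end testing without human-subjects data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
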