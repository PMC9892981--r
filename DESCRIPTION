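Package: msacoach
Title: Metabolic Syndrome Age Scoring and Digital Health Coaching Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing a one-group pre/post digital
    health coaching trial in metabolic syndrome (MS). Computes Metabolic
    Syndrome Age (MSA) from sex-specific linear biomarker equations over
    waist circumference, pulse pressure, fasting blood sugar, triglycerides,
    high-density lipoprotein cholesterol and chronological age; classifies
    participants against the five harmonized MS criteria into normal, risk
    and MS groups; derives lifestyle metrics (weekly ethanol grams, sleep
    adequacy, monthly step-count means); assigns participants to five
    coaching management groups by their poorest sex/age-referenced
    indicator; and runs the pre/post comparison (paired t tests, chi-square
    tests) into publication-shaped summary tables. A calibrated synthetic
    cohort generator (truncated-normal marginals joined by a Gaussian
    copula, staged attrition) makes the whole pipeline exercisable without
    any participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
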