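Package: gdikit
Title: Gene-Diet Interaction Analysis for Type 2 Diabetes Genetic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how dietary exposures modify polygenic risk of
    type 2 diabetes. Builds weighted and un-weighted genetic risk scores from
    additive SNP dosages, codes food-frequency-questionnaire fruit intake into
    ordinal exposure levels, derives glycemic phenotypes (diabetes status by
    ADA thresholds, HOMA-beta, HOMA-IR), and tests gene-by-diet interactions
    on diabetes status and quantitative glycemic traits with its own
    iteratively-reweighted-least-squares likelihood machinery (Wald and
    likelihood-ratio tests). Includes a per-SNP two-degree-of-freedom joint
    screening cascade with Bonferroni follow-up, a synthetic cohort generator
    emulating the statistical structure of a large community-based Chinese
    cohort, and deterministic tabular reporting with a small command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
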