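Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of FAERS-style spontaneous
    adverse event report databases: reading and writing the quarterly ASCII
    tables (DEMO, DRUG, REAC, THER, INDI, OUTC), case deduplication by the FDA
    rule, primary-suspect cohort extraction, preferred-term and organ-class
    2x2 contingency building, four disproportionality statistics (reporting
    odds ratio, proportional reporting ratio with chi-square, the BCPNN
    information component, and the empirical-Bayes gamma-Poisson shrinker
    EBGM), Weibull time-to-onset modelling with failure-type classification,
    subgroup and sensitivity analyses, and a synthetic spontaneous-reporting
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
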