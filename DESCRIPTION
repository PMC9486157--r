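Package: fqsignal
Title: Pharmacovigilance Signal Detection for Fluoroquinolone Tendon Injury in FAERS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for disproportionality analysis of
    fluoroquinolone-associated tendonitis and tendon rupture in the FDA
    Adverse Event Reporting System (FAERS). Parses FAERS ASCII quarterly
    archives, deduplicates reports by the FDA-recommended rule, extracts a
    primary-suspect cohort against a drug lexicon and MedDRA Preferred Term
    target list, and computes four disproportionality statistics (reporting
    odds ratio, proportional reporting ratio, information component, and
    empirical Bayes geometric mean) with interval bounds, signal-positivity
    criteria, and stratified variants by sex, age group, and administration
    route. Also produces clinical-characteristics tables, serious-outcome
    proportions, time-to-onset quartiles and histograms, and a synthetic
    FAERS quarter generator with planted signals so every stage is testable
    without a FAERS download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
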