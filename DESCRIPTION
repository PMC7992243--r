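Package: ardscreen
Title: Automated Berlin-Definition ARDS Screening of ICU EHR Extracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based computable phenotyping of acute respiratory distress
    syndrome (ARDS) per the Berlin definition from flat-file intensive care
    unit (ICU) electronic health record extracts. Implements the sequential
    screening gates (research authorization and age, first PEEP >= 5 cm H2O
    in an ICU area as time zero, PaO2/FiO2 ratio <= 300 from lab or
    nearest-in-time vital-sign FiO2, bilateral-infiltrate keyword match on
    chest X-ray reports, pulmonary-fibrosis exclusion, invasive-ventilation
    duration, ARDS risk factors, and cardiogenic-edema exclusion), a seeded
    synthetic ICU cohort generator with controllable prevalence and
    documented false-negative archetypes, diagnostic-accuracy metrics
    (sensitivity, specificity, PPV, NPV) against gold-standard labels, and
    exhaustive reconstruction of integer confusion tables from published
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
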