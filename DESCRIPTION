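Package: dvconcord
Title: Concordance Between Mental-Illness Mentions in Police Narratives and
    Hospital Diagnoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for measuring event-level concordance between
    mental-illness mentions text-mined from domestic-violence police event
    narratives and mental-health diagnoses held in hospital admission (APDC)
    and emergency-department (EDDC) records. Provides a gazetteer plus
    semantic-anchor rule grammar for role-attributed mention extraction, an
    ICD-9/SNOMED-CT to ICD-10 code harmonizer with first-level roll-up of the
    Mental and Behavioural Disorders chapter, temporal window-period record
    linkage on exact person identifiers, 2x2 cross-tabulation and per-group
    concordance reporting, and a labelled synthetic-cohort generator so that
    every stage can be exercised without access to confidential administrative
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
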