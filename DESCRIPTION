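Package: hbpalert
Title: Urgent-Notification Triage and Association Analysis for Home Blood
    Pressure Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes 14-day home blood pressure measurement streams into
    time-of-day period averages, applies hypertension-grade triage criteria
    (JSH2009 thresholds) to decide urgent notifications, flags laboratory
    panels against clinical reference ranges, and analyses co-occurrence of
    laboratory abnormality categories among notified participants with
    Yates-corrected chi-squared and Fisher exact tests under Bonferroni
    control. Includes a paired (McNemar) analysis of pre/post notification
    care-seeking behaviour, a synthetic-cohort generator for end-to-end
    validation, and a batch pipeline that persists every stage as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
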