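Package: fraudsieve
Title: Fraud and Low-Quality Response Screening for Online Health Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to screen online survey cohorts for fraudulent and
    low-quality responses of the kind produced by bots, survey farms, and
    careless respondents. Implements a battery of per-case indicator
    detectors (completion-time bands, straight-lining, duplicate and
    patterned open-text responses, honeypot hidden-item responses, and
    consistency checks between reported location, zip-code prefix,
    timestamp time zone, treatment facility, and referral source), a
    rule-based case classifier (fraudulent, suspicious, legitimate), and
    cohort-level summary reporting. Includes a persona-mixture simulator
    of synthetic respondents (legitimate, satisficer, bot, survey farm)
    and a deterministic replication fixture generator for end-to-end
    pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
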