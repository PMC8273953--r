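Package: phesnorm
Title: Population Normalisation and Scoring of the Psychometric Hepatic
    Encephalopathy Score (PHES)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits age- and education-adjusted normative models for the five
    tests of the porto-systemic encephalopathy battery (NCT-A, NCT-B, SDT,
    LTT, DST), converts raw test results into banded standard-deviation
    component scores and the integer PHES total, derives population cut-offs
    at mean minus two standard deviations, classifies minimal hepatic
    encephalopathy (MHE), and summarises cirrhotic cohorts with prevalences,
    odds ratios with Woolf confidence intervals and complete-case group
    comparisons. Ships the published Cameroonian normative constants and a
    seeded synthetic-cohort generator for volunteers and cirrhotic patients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
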