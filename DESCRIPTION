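Package: cohortdrift
Title: Attrition Bias in Longitudinal Cohorts of Older People
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models how the prevalence of a fixed risk factor drifts apart
    between a longitudinal study cohort and its target population under two
    attrition processes: death, which removes individuals from both, and
    non-death attrition (withdrawal, loss to follow up), which removes
    individuals from the cohort only. Provides the deterministic prevalence
    recursions and canonical hypothetical scenarios, a synthetic generator
    for multi-wave cohorts of older women with the attrition structure of
    the Australian Longitudinal Study on Women's Health (ALSWH) 1921-26
    cohort, a multinomial logistic attrition analysis with the field's
    reference-category and variable-retention conventions, and
    survey-weighted prevalence comparison against external population
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    nnet,
    stats,
    utils,
    jsonlite,
    yaml,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
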