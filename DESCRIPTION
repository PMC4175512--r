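Package: maicsurv
Title: Matching-Adjusted Indirect Comparisons for Survival Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Matching-adjusted indirect comparison (MAIC) of time-to-event
    outcomes between a trial with individual patient data and a trial reported
    only in aggregate. Implements method-of-moments exponential-tilting weight
    estimation with exact balance on reported medians and proportions,
    reconstruction of pseudo individual patient data from digitized
    Kaplan-Meier curves with numbers at risk, weighted Kaplan-Meier and
    weighted Cox proportional-hazards comparisons with weight-robust variance,
    Bucher anchored indirect comparisons, number-needed-to-treat summaries,
    placebo-arm negative-control diagnostics, placebo-adjusted adverse-event
    odds ratios, and a synthetic two-trial generator with
    progression-triggered crossover for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
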