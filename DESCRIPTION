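Package: factmams
Title: Factorial and Multi-Arm Multi-Stage Clinical Trial Designs with
    Familywise Error Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design engine for superiority trials that evaluate two
    treatments and their combination against a common control with a
    normally distributed endpoint and known standard deviation.  Computes
    the joint trivariate normal law of the treatment-versus-control
    z-statistics for 2x2 factorial and multi-arm (Dunnett) designs,
    familywise-error-controlling critical values, disjunctive power,
    sample sizes and allocation-ratio optimisation, calibrates two-stage
    multi-arm multi-stage (MAMS) designs with O'Brien-Fleming efficacy
    boundaries and a fixed futility bound, and provides a seeded
    patient-level simulator under the full interaction model for
    empirical operating characteristics, including the consequences of
    synergistic or antagonistic treatment interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mvtnorm,
    pracma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
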