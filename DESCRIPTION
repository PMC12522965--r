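Package: icdcea
Title: Markov Cohort Cost-Effectiveness Analysis of ICD Therapy Versus
    Pharmacotherapy for Cardiac Arrhythmia
Version: 0.1.0
Authors@R: person("icdcea", "maintainers", email = "icdcea@example.org",
    role = c("aut", "cre"))
Description: Lifetime Markov cohort state-transition model comparing
    implantable cardiac defibrillator (ICD) therapy with pharmaceutical
    therapy for cardiac arrhythmia: cohort simulation with discounted
    cost and QALY accrual, ICER/ACER/net-monetary-benefit computation
    against a willingness-to-pay threshold, deterministic (tornado,
    two-way) and probabilistic (Monte-Carlo, acceptability-curve)
    sensitivity analyses with beta/gamma method-of-moments parameter
    distributions, and least-squares calibration of unpublished
    transition probabilities to reported lifetime outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
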