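Package: aaascreen
Title: Cost-Effectiveness of One-Time Abdominal Aortic Aneurysm Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort model for the economic evaluation of a one-time
    population-based ultrasound screening program for abdominal aortic
    aneurysm (AAA) in 65-year-old men, compared with no screening. Implements
    an eleven-status cohort model run on 3-month cycles over a lifetime
    horizon with half-cycle correction and discounting, base-case incremental
    cost-effectiveness analysis (cost per QALY and per life-year), one-way
    deterministic sensitivity analysis with tornado ranking, and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves.
    Parameter uncertainty is specified as point estimates with ranges;
    sampling distributions (beta, gamma, normal, Dirichlet) are derived by
    method of moments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
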