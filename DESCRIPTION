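Package: drtcea
Title: Cost-Effectiveness Analysis of Pretreatment HIV Drug Resistance Testing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Markov cohort model and individual-level microsimulation for the
    cost-effectiveness of pretreatment genotypic HIV drug-resistance testing
    versus empiric dolutegravir-based first-line therapy. Implements a
    three-state (HIV, AIDS, death) annual-cycle model with treatment-line
    dynamics, discounted cost and QALY accumulation, incremental
    cost-effectiveness ratios and net monetary benefit, one-way deterministic
    sensitivity analysis (tornado), and probabilistic sensitivity analysis
    with Beta/Gamma parameter distributions and cost-effectiveness
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
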