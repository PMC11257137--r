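Package: svyrake
Title: Raking Weights and Benchmark Evaluation for Non-Probability Health Surveys
Version: 0.1.0
Authors@R: person("svyrake", "maintainers", email = "svyrake@example.org", role = c("aut", "cre"))
Description: Tools for calibrating respondent-level categorical microdata from
    non-probability samples (such as volunteer research cohorts) to known
    population marginal proportions by raking (iterative proportional
    fitting). Includes discrepancy-based screening of candidate raking
    variables, benchmark-comparison tables with weighted and unweighted
    prevalence estimates, Kish effective-sample-size diagnostics, a synthetic
    microdata generator with a logistic self-selection model for offline
    testing, and a command-line interface covering the full
    simulate/select/rake/evaluate workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
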