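Package: bayesinterim
Title: Bayesian Interim Monitoring of Randomized Trials with Dynamic
    Borrowing from Historical Controls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for benefit-risk assessment at scheduled interim
    analyses of two-arm randomized trials, built around an acute myeloid
    leukemia induction-trial setting. Provides a synthetic patient-level
    trial simulator (staggered accrual, Weibull event-free survival,
    binary response and safety endpoints), propensity-score matching of
    an external historical control cohort, Bayesian beta-binomial and
    Weibull proportional-hazards models with commensurate-prior dynamic
    borrowing and a self-contained adaptive Metropolis-within-Gibbs
    sampler, posterior hazard-ratio threshold probabilities, interim
    report orchestration, and a conventional group-sequential comparator
    with Lan-DeMets O'Brien-Fleming error spending, boundary solving by
    recursive numerical integration, and simulation-based operating
    characteristics of the log-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
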