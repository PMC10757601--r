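Package: brcacea
Title: Cost-Utility and Budget-Impact Modelling of BRCA1/2 Testing with
    Cascade Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-analytic modelling of germline BRCA1/2 testing in
    high-risk breast-cancer patients and their relatives: decision-tree
    risk stratification into management groups, a lifetime Markov cohort
    model over breast and ovarian cancer health states with
    time-since-diagnosis tunnel clocks, cost-utility results (ICER, net
    monetary benefit), one-way and probabilistic sensitivity analyses
    with cost-effectiveness acceptability curves, a national five-year
    budget-impact projection, and a synthetic interview-microdata
    generator for testing the parameter-estimation stage. All model
    inputs are declared as mean/SE parameters with moment-matched Beta
    or Gamma sampling distributions and live in a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
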