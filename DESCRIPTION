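Package: epicost
Title: Episode-Based Hospital Cost Analysis for Type 2 Diabetes Complications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs complication episodes from longitudinal hospital
    diagnosis records of people with type 2 diabetes, attributes deflated
    hospital costs to one-year observation windows around each episode,
    fits per-complication gamma regression models with log link and
    cluster-robust (sandwich) inference, computes average marginal effects,
    and simulates predicted one-year cost distributions for covariate
    profiles via Cholesky draws from the coefficient covariance. Ships a
    synthetic registry generator with known ground truth so the whole
    pipeline is testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
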