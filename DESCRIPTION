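Package: perploss
Title: Valuing Non-Financial Losses to Traffic-Accident Perpetrators from
    Stated-Preference Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for double-bounded dichotomous-choice (DBDC) contingent
    valuation of the non-financial losses borne by the perpetrators of fatal
    traffic accidents. Simulates stated-preference survey populations with a
    logistic random-utility purchase model, constructs the six-record DBDC
    response dataset with rational imputation, fits pooled binomial-logit
    indirect-utility models with McFadden and Estrella fit statistics and
    per-respondent cluster-robust covariances, runs internal and external
    scope tests, converts fits into median and mean willingness-to-pay for
    accident-risk-reducing devices, anchors perpetrator losses to a victim
    reference value through perpetrator-to-victim WTP ratios, elicits CRRA
    risk-aversion coefficients from lottery-choice switch points, and
    decomposes multiplicative accident-loss identities into factor variation
    rates with a residual.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
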