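Package: iedina
Title: Item-Explanatory Higher-Order DINA Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cognitive diagnosis modelling with explanatory item parameters.
    Fits the higher-order DINA model and its item-explanatory extensions, in
    which the guessing or slipping parameter is decomposed on the logit scale
    into a linear combination of manifest item features, optionally with an
    item-level residual. Estimation is by Metropolis-within-Gibbs MCMC with
    exact latent-profile enumeration and conjugate truncated-Beta item
    updates. Includes posterior predictive model checking, DIC, Wald tests of
    feature coefficients, a two-step regression alternative, an item-text
    linguistic feature extractor with collinearity screening, a synthetic-data
    simulator, and a parameter-recovery study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
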