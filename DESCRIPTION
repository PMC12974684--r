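Package: survtransfer
Title: Transfer Learning of Optimal Individualized Treatment Regimes with
    Right-Censored Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Doubly robust transfer learning for estimating optimal
    individualized treatment regimes (ITRs) and their value functions with
    right-censored survival outcomes, combining a selection-biased source
    sample (e.g. a randomized trial) with a design-weighted target sample
    under covariate shift.  Implements an augmented calibration-weighted
    (ACW) estimator of counterfactual survival curves built on the efficient
    influence function, with censoring-martingale augmentation,
    entropy-balancing calibration weights, parametric (logistic / Cox with
    Breslow baselines) and random-forest nuisance models, K-fold
    cross-fitting, global stochastic policy search over linear treatment
    rules, nonparametric bootstrap inference, and a synthetic-data engine
    for simulation studies with survival and censoring times drawn from
    Gompertz-type hazards.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    ranger,
    withr
Config/testthat/edition: 3
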