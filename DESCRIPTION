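Package: hccea
Title: Cost-Effectiveness of First-Line Sintilimab Plus IBI305 Versus
    Sorafenib in Unresectable Hepatocellular Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (stable disease, progressive disease, death)
    time-inhomogeneous Markov cohort model for the economic evaluation of
    first-line sintilimab plus IBI305 against sorafenib in unresectable
    hepatocellular carcinoma, from the Chinese payer perspective.
    Parametric survival curves (exponential, Weibull, gamma, log-normal,
    log-logistic, Gompertz) are fitted to reconstructed pseudo-individual
    patient data by censored maximum likelihood and ranked by AIC/BIC;
    per-cycle transition probabilities are derived from conditional
    survival. Includes Guyot-style reconstruction of individual patient
    data from digitized Kaplan-Meier coordinates, one-way (tornado)
    sensitivity analysis, threshold price-reduction search, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, and
    synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    graphics,
    utils,
    tibble,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
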