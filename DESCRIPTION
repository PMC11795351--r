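Package: gmethods
Title: Causal Inference Estimators for the Average Treatment Effect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimators of the average treatment effect (ATE) of a binary
    treatment on a binary or bounded outcome from observational cohort data:
    nonparametric and parametric g-computation (standardization), inverse
    probability of treatment weighting with Horvitz-Thompson and stabilized
    (Hajek) weights, marginal structural models, the doubly robust IPTW-RA and
    AIPTW estimators, and targeted maximum likelihood estimation (TMLE) with
    influence-function inference and an optional cross-validated ensemble
    (super learner) for the nuisance models.  Includes propensity-score balance
    and overlap diagnostics, weight trimming and truncation, bootstrap
    confidence intervals (normal, percentile, bias-corrected), synthetic cohort
    generators with an exact truth oracle, and a Monte Carlo benchmarking
    harness.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
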