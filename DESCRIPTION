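Package: ordbagg
Title: Bootstrap Ensemble Classification of Ordinal Outcomes in
    High-Dimensional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ensemble classifier for ordinal outcomes (e.g., tumor grade,
    disease severity) measured alongside high-dimensional genomic
    covariates (p >> n). Five constituent ordinal classifiers -- an
    L1-penalized backward continuation-ratio model, its path-wise
    variant, an L1-penalized cumulative-logit model, a cumulative-logit
    model fit by generalized monotone incremental forward stagewise
    (GMIFS) updates, and an ordinal forest -- are trained on bootstrap
    resamples, scored out-of-bag on four ordinal metrics (mean absolute
    error, Kendall's tau-b, accuracy, Goodman-Kruskal gamma), ranked,
    and rank-aggregated under Spearman's footrule to pick one winner per
    bootstrap; final predictions are obtained by majority vote across
    the per-bootstrap winners. Includes simulation designs for latent
    continuous outcomes with AR(1)-correlated predictors, unequal class
    sizes, proportional-odds violations, and mean-shifted independent
    predictors, plus a Monte-Carlo benchmark driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
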