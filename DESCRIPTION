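Package: feedbackbias
Title: Hierarchical Bayesian Modelling of Self-Evaluation Updating After
    Social Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how positive versus neutral social feedback
    updates self-efficacy and self-evaluation ratings in a judged
    public-speaking task. Implements the constrained feedback-assignment
    algorithm used to generate the task schedule, a synthetic-cohort
    generator with known ground truth, a hierarchical Bayesian multivariate
    normal model with condition-specific subject-level covariance matrices
    fitted by a conjugate Gibbs sampler, per-subject positive-update-bias
    indices derived from correlation-matrix contrasts, K-fold
    cross-validated ELPD model comparison, group-level highest-density
    interval inference, posterior predictive checks, varimax PCA symptom
    profiling, bootstrap mediation, and classical validation statistics
    (Friedman with Kendall's W, Wilcoxon signed-rank, paired t with Cohen's
    d, repeated-measures ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    coda,
    withr
Config/testthat/edition: 3
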