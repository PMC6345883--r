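Package: tempar
Title: Bayesian Dynamic Autoregressive Differential Expression for
    Longitudinal RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects temporally differential expression in within-subject
    longitudinal RNA-seq experiments with a per-feature Bayesian
    Poisson-gamma (negative binomial) model in which a subject-level gamma
    frailty shared across time points induces the repeated-measurement
    dependence and a log-scale temporal parameter is tested through its
    posterior tail probabilities, estimated by Metropolis-within-Gibbs MCMC.
    Includes the surrounding pipeline: technical-replicate pooling,
    median-of-ratios normalization, correlation/MDS/PCA sample diagnostics
    with outlier flagging, replicate-based estimation of unwanted-variation
    covariates (lane and sequencing-batch effects) incorporated into the
    model, a Fisher exact static comparator, and a ground-truth simulator of
    longitudinal count data with lanes, batches, technical replicates and a
    degraded outlier library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
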