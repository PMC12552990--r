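Package: c9methpred
Title: Blood DNA Methylation Detection of C9orf72 Repeat Expansion Carriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Covariate-adjusted per-probe differential methylation analysis of
    EPIC-style methylation arrays on the M-value scale with empirical-Bayes
    variance moderation, a permutation-derived genome-wide significance
    threshold, a locus-restricted L1-penalised logistic classifier for
    C9orf72 repeat-expansion carrier status with repeated-split evaluation
    and array-platform degradation comparison, frozen-model application to
    independent cohorts, and a synthetic-cohort generator that makes the
    whole pipeline reproducible without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    limma,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
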