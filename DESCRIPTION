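Package: gcnfuse
Title: Co-Expression Module Eigengenes, Lasso-Cox Selection and Similarity
    Network Fusion for Survival Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative survival-prognosis workflow for paired
    transcriptomic platforms measured on the same patient cohort. Gene
    co-expression modules are mined with the local maximum Quasi-Clique
    Merging (lmQCM) greedy algorithm on absolute Spearman correlation
    networks, summarized into per-sample eigengenes (first principal
    component), compared across platforms for uniqueness (Jaccard index and
    Fisher exact overlap test) and coherence (Correlation Index with a
    permutation p-value), screened for survival association with a
    cross-validated lasso-regularized Cox proportional hazards model, and
    integrated by Similarity Network Fusion of per-platform patient
    similarity networks followed by spectral clustering and Kaplan-Meier /
    log-rank survival comparison. A synthetic cohort generator with planted
    co-expression modules and proportional-hazards survival provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
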