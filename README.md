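# gcnfuse

Integrative survival prognosis from paired transcriptomic platforms via
co-expression module eigengenes, lasso-Cox feature selection, and
Similarity Network Fusion.

## What problem this solves

When the same tumor cohort is profiled on two platforms (say, a
microarray and RNA-seq), each platform captures co-expression structure
the other partly misses. For outcomes like survival of high-risk
neuroblastoma patients — where clinical staging stratifies poorly —
that complementary structure is worth integrating rather than discarding.
`gcnfuse` implements the full module-level workflow for analysts working
with two expression matrices (genes × samples) and a clinical follow-up
table:

1. **Module mining.** Per platform, a weighted gene co-expression network
   with edge weights `|Spearman ρ|`, mined by local maximum Quasi-Clique
   Merging (lmQCM): seed at locally maximal edges with weight ≥ γ
   (default 0.80), grow greedily while the module density stays above the
   adaptive fraction `1 − 1/(2α(k + 1 + t))` of its current value, merge
   clusters overlapping by ≥ β = 0.4. Modules may overlap, matching genes'
   participation in multiple processes.
2. **Eigengenes.** Each module is summarized as the first principal
   component of its z-scored submatrix, one value per patient, unit
   variance, sign-aligned with the module mean.
3. **Cross-platform comparison.** A module is *unique* to its platform iff
   against every module of the other platform the Jaccard index is < 0.05
   and the one-sided Fisher exact overlap p is > 0.05. Module coherence is
   the Correlation Index `C = ‖W − I‖²_F / K²` with a permutation p-value
   from size-matched random gene sets.
4. **Survival screening.** A lasso-regularized Cox model on the eigengenes
   (inner 10-fold CV for the penalty; optional leave-one-out outer CV with
   consensus aggregation) yields per-patient risk indices, dichotomized at
   the training median and tested by Kaplan–Meier / log-rank.
5. **Integration.** Patient similarity networks built from each platform's
   selected, platform-unique eigengenes are fused by Similarity Network
   Fusion (cross-diffusion with a K-nearest-neighbor kernel; K = 30,
   μ = 0.8, 20 iterations), the fused network is clustered spectrally, and
   the strata are compared by the log-rank test.

A synthetic cohort generator (`cohort_config()` / `generate_cohort()`)
plants known modules, latent factors, optional patient subtypes and
proportional-hazards survival, so every stage is testable against ground
truth.

## Worked example

```r
library(gcnfuse)

cfg <- cohort_config(
  n_samples = 150, n_genes_per_platform = 300,
  shared_modules = list(S1 = list(size = 40, cor = 0.8),
                        S2 = list(size = 30, cor = 0.8)),
  unique_modules_platform1 = list(
    U1 = list(size = 25, cor = 0.8, subgroup_shift = c(0, 1.2, 0))),
  unique_modules_platform2 = list(
    U2 = list(size = 25, cor = 0.8, subgroup_shift = c(0, 0, 1.2))),
  hazard_coefficients = c(U1 = 0.7, U2 = 0.7),
  censoring_rate_target = 0.3,
  subgroup_probs = c(0.5, 0.25, 0.25),
  seed = 1)
cohort <- generate_cohort(cfg)

res <- run_pipeline(cohort$expr1, cohort$expr2, cohort$survival,
                    n_clusters = 3, seed = 1)
res$selected1
#> [1] "M3"
res$selected2
#> [1] "R3"
sapply(res$survival_tests, function(t) signif(t$p_value, 3))
#>      platform1_all platform1_selected      platform2_all platform2_selected
#>           5.59e-02           5.85e-06           1.05e-03           1.15e-07
#>          snf_fused
#>           5.17e-07
```

The cohort has two shared "noise" modules and one survival-driving unique
module per platform, activated in two distinct patient subtypes. The lasso
selects exactly the two informative eigengenes (`M3` and `R3` are the
mined versions of the planted `U1` and `U2`). The log-rank p-values show
the two effects the workflow is built around: per platform, clustering on
the *selected* eigengenes stratifies survival far better than clustering
on all eigengenes (5.6e-2 → 5.9e-6 and 1.1e-3 → 1.2e-7), and the
SNF-fused network (5.2e-7) reaches the same discrimination using both
platforms' unique modules at once. Single runs fluctuate; the property
that fusion beats *either* platform alone holds in geometric mean over
replicates and is asserted by the test suite.

Individual stages are exported for piecemeal use:
`spearman_weight_matrix()`, `normalize_weights()`, `lmqcm_mine()`,
`eigengene_matrix()`, `unique_modules()`, `correlation_index_p()`,
`module_stability()`, `lasso_cox_fit()`, `loocv_risk_indices()`,
`km_estimate()`, `logrank_test()`, `affinity_kernel()`, `snf_fuse()`,
`spectral_cluster()`, plus TSV/GMT/JSON I/O helpers
(`read_expression()`, `read_clinical()`, `write_modules_gmt()`,
`write_report()`).

See `vignettes/integrative-survival-workflow.Rmd` for the model, the
parameter meanings and defaults, and the design decisions.

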