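make_features <- function(p, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(p * n), p, n,
         dimnames = list(sprintf("E%d", seq_len(p)), sprintf("P%03d", seq_len(n))))
}

test_that("median_split dichotomizes with ties going low", {
  g <- median_split(c(1, 2, 3, 4), 2.5)
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(2.5, 2.5)), "low")
  expect_warning(median_split(c(1, 1, 1), 1), "identical")
})

test_that("consensus selection counts fold frequencies", {
  sets <- c(rep(list(c("E1", "E2")), 6), rep(list("E1"), 4))
  expect_equal(consensus_selection(sets, 0.5), c("E1", "E2"))
  expect_equal(consensus_selection(sets, 0.7), "E1")
  expect_equal(consensus_selection(list(character()), 0.5), character())
  expect_error(consensus_selection(list()), "empty")
})

test_that("KM estimator matches hand product-limit arithmetic", {
  km <- km_estimate(data.frame(time = c(5, 8, 12), event = c(1, 1, 1)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$step(c(4, 6, 9, 13)), c(1, 2 / 3, 1 / 3, 0))
  km2 <- km_estimate(data.frame(time = c(5, 8, 12), event = c(1, 0, 1)))
  expect_equal(km2$step(c(6, 9)), c(2 / 3, 2 / 3))
  expect_equal(km2$step(13), 0)
  km3 <- km_estimate(data.frame(time = c(3, 6), event = c(0, 0)))
  expect_true(all(km3$surv == 1))
  # non-increasing from 1
  set.seed(11)
  km4 <- km_estimate(data.frame(time = rexp(50), event = rbinom(50, 1, 0.7)))
  expect_true(all(diff(km4$surv) <= 0))
  expect_lte(max(km4$surv), 1)
})

test_that("log-rank agrees with direct O-E enumeration and handles edge cases", {
  surv <- data.frame(time = c(1, 2, 3, 10, 11, 12), event = 1)
  grp <- rep(c("A", "B"), each = 3)
  lt <- logrank_test(surv, grp)
  expect_equal(lt$statistic, oracle_logrank_chisq(surv$time, surv$event, grp),
               tolerance = 1e-10)
  expect_equal(lt$df, 1)
  # label swap invariance
  lt2 <- logrank_test(surv, rep(c("B", "A"), each = 3))
  expect_equal(lt2$statistic, lt$statistic)
  # identical groups -> statistic 0, p = 1
  surv2 <- data.frame(time = rep(c(1, 2, 3), 2), event = 1)
  lt3 <- logrank_test(surv2, rep(c("A", "B"), each = 3))
  expect_equal(lt3$statistic, 0, tolerance = 1e-12)
  expect_equal(lt3$p_value, 1)
  expect_error(logrank_test(surv, rep("A", 6)), "2 non-empty groups")
  # oracle check with censoring and a 3-group run
  set.seed(12)
  surv3 <- data.frame(time = rexp(60), event = rbinom(60, 1, 0.7))
  g3 <- sample(c("x", "y"), 60, replace = TRUE)
  lt4 <- logrank_test(surv3, g3)
  expect_equal(lt4$statistic, oracle_logrank_chisq(surv3$time, surv3$event, g3),
               tolerance = 1e-8)
  lt5 <- logrank_test(surv3, sample(c("x", "y", "z"), 60, replace = TRUE))
  expect_equal(lt5$df, 2)
  expect_gte(lt5$p_value, 0)
  expect_lte(lt5$p_value, 1)
})

test_that("lasso-Cox recovers a strongly informative feature with a positive sign", {
  set.seed(13)
  hits <- 0
  for (rep in 1:20) {
    feats <- make_features(4, 250, seed = 100 + rep)
    set.seed(200 + rep)
    surv <- survival_from_linpred(feats["E1", ], 0.05, 0.25, colnames(feats))
    fit <- lasso_cox_fit(feats, surv, seed = rep)
    if ("E1" %in% fit$selected_features && fit$coefficients["E1"] > 0)
      hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("fit reproducibility, fold accounting and degenerate inputs", {
  feats <- make_features(3, 40, seed = 3)
  set.seed(3)
  surv <- survival_from_linpred(feats["E1", ] * 0.8, 0.1, 0.2, colnames(feats))
  f1 <- lasso_cox_fit(feats, surv, seed = 7)
  f2 <- lasso_cox_fit(feats, surv, seed = 7)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_error(lasso_cox_fit(feats, transform(surv, event = 0)), "2 events")
  expect_warning(lasso_cox_fit(feats, surv[1:8, ], seed = 1), "folds")
  # a single-feature matrix is handled via the constant pad
  f3 <- lasso_cox_fit(feats["E1", , drop = FALSE], surv, seed = 5)
  expect_equal(f3$feature_labels, "E1")
})

test_that("risk ordering is invariant to adding a constant to a feature", {
  feats <- make_features(3, 150, seed = 21)
  set.seed(21)
  surv <- survival_from_linpred(feats["E1", ], 0.05, 0.2, colnames(feats))
  f1 <- lasso_cox_fit(feats, surv, seed = 2)
  feats2 <- feats
  feats2["E1", ] <- feats2["E1", ] + 5
  f2 <- lasso_cox_fit(feats2, surv, seed = 2)
  expect_equal(order(f1$risk), order(f2$risk))
})

test_that("LOOCV produces one outer fit per sample and is seed-stable", {
  feats <- make_features(2, 25, seed = 31)
  set.seed(31)
  surv <- survival_from_linpred(feats["E1", ] * 1.2, 0.1, 0.15, colnames(feats))
  cv1 <- loocv_risk_indices(feats, surv, inner_folds = 5, seed = 11)
  expect_equal(nrow(cv1$risk), 25)
  expect_length(cv1$fold_selected, 25)
  cv2 <- loocv_risk_indices(feats, surv, inner_folds = 5, seed = 11)
  expect_identical(cv1, cv2)
  expect_true(all(cv1$risk$group %in% c("low", "high")))
})

test_that("selected-feature risk split separates survival better than noise-diluted risk", {
  set.seed(41)
  ratios <- replicate(10, {
    feats <- make_features(8, 200, seed = sample.int(1e6, 1))
    surv <- survival_from_linpred(feats["E1", ] + feats["E2", ], 0.05, 0.2,
                                  colnames(feats))
    informative <- colSums(feats[c("E1", "E2"), ])
    diluted <- colSums(feats)  # equal weights on all 8, 6 of them noise
    p_inf <- logrank_test(surv, median_split(informative, median(informative)))$p_value
    p_dil <- logrank_test(surv, median_split(diluted, median(diluted)))$p_value
    log(p_inf) - log(p_dil)
  })
  expect_lt(mean(ratios), 0)  # geometric-mean improvement
})
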