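#' Fit a lasso-regularized Cox proportional hazards model
#'
#' The penalty is chosen by `inner_folds`-fold cross-validated partial
#' likelihood deviance over a decreasing penalty path (glmnet), then the
#' final model is refit on all provided samples at the chosen penalty.
#' Features are the rows of an eigengene matrix; samples are aligned to the
#' clinical table by sample id.
#'
#' @param features Numeric matrix, features (eigengenes) x samples, with
#'   feature labels as rownames and sample ids as colnames.
#' @param survival Data frame with columns `sample_id`, `time`, `event`.
#' @param inner_folds Number of cross-validation folds (default 10; reduced
#'   with a warning when there are fewer samples).
#' @param seed Optional integer seed controlling fold assignment.
#' @param penalty `"min"` (deviance-minimizing penalty, default) or `"1se"`
#'   (one-standard-error rule).
#' @return Object of class `risk_model`: `feature_labels`, `coefficients`
#'   (named), `lambda`, `penalty_rule`, `selected_features` (nonzero
#'   coefficients), `training_median_risk` (median linear predictor) and
#'   `risk` (training linear predictors, named by sample).
#' @export
lasso_cox_fit <- function(features, survival, inner_folds = 10L, seed = NULL,
                          penalty = c("min", "1se")) {
  penalty <- match.arg(penalty)
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  if (!all(survival$sample_id %in% colnames(features)))
    stop("samples in clinical table missing from feature matrix", call. = FALSE)
  if (sum(survival$event) < 2)
    stop("cannot fit a Cox model with fewer than 2 events", call. = FALSE)
  x <- t(features[, survival$sample_id, drop = FALSE])
  y <- survival::Surv(survival$time, survival$event)
  n <- nrow(x)
  nf <- inner_folds
  if (n < nf) {
    warning("fewer samples than folds; reducing to ", max(3L, n %/% 2L), " folds")
    nf <- max(3L, n %/% 2L)
  }
  if (!is.null(seed)) set.seed(seed)
  foldid <- sample(rep(seq_len(nf), length.out = n))
  dummy <- ncol(x) == 1L  # glmnet needs >= 2 columns; pad with a constant
  if (dummy) x <- cbind(x, `.const.` = 0)
  cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                          type.measure = "deviance")
  lam <- if (penalty == "min") cv$lambda.min else cv$lambda.1se
  co <- as.numeric(stats::coef(cv, s = lam))
  names(co) <- colnames(x)
  if (dummy) {
    co <- co[names(co) != ".const."]
    x <- x[, names(co), drop = FALSE]
  }
  risk <- drop(x %*% co)
  names(risk) <- survival$sample_id
  structure(list(
    feature_labels = names(co),
    coefficients = co,
    lambda = lam,
    penalty_rule = penalty,
    selected_features = names(co)[co != 0],
    training_median_risk = stats::median(risk),
    risk = risk
  ), class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("lasso-Cox risk model (penalty", format(x$lambda, digits = 4),
      "by", x$penalty_rule, "rule)\n")
  cat("  selected:", if (length(x$selected_features))
    paste(x$selected_features, collapse = ", ") else "<none>", "\n")
  cat("  training median risk:", format(x$training_median_risk, digits = 4), "\n")
  invisible(x)
}

#' Predict risk indices (Cox linear predictors) for new samples
#'
#' @param model A `risk_model`.
#' @param features Features x samples matrix containing the model's
#'   feature labels.
#' @return Named numeric vector of linear predictors.
#' @export
predict_risk <- function(model, features) {
  stopifnot(inherits(model, "risk_model"))
  missing <- setdiff(model$feature_labels, rownames(features))
  if (length(missing))
    stop("feature(s) absent: ", paste(missing, collapse = ", "), call. = FALSE)
  drop(crossprod(features[model$feature_labels, , drop = FALSE], model$coefficients))
}

#' Leave-one-out cross-validated risk indices
#'
#' The outer level is leave-one-out: each sample in turn is held out, a
#' lasso-Cox model is fit on the remaining samples (inner `inner_folds`-fold
#' CV chooses the penalty), and the held-out sample receives the linear
#' predictor of that model and a low/high group label relative to the
#' training fit's median risk. The features selected by each outer fold are
#' recorded for consensus aggregation.
#'
#' @inheritParams lasso_cox_fit
#' @return List with `risk` (data frame `sample_id`, `risk`, `group`) and
#'   `fold_selected` (list of selected-feature label sets, one per sample).
#' @export
loocv_risk_indices <- function(features, survival, inner_folds = 10L,
                               seed = NULL, penalty = c("min", "1se")) {
  penalty <- match.arg(penalty)
  n <- nrow(survival)
  if (is.null(seed)) seed <- 0L
  risk <- numeric(n)
  group <- character(n)
  fold_selected <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- lasso_cox_fit(features, survival[-i, , drop = FALSE],
                         inner_folds = inner_folds, seed = seed + i,
                         penalty = penalty)
    r <- predict_risk(fit, features[, survival$sample_id[i], drop = FALSE])
    risk[i] <- r
    group[i] <- as.character(median_split(r, fit$training_median_risk))
    fold_selected[[i]] <- fit$selected_features
  }
  list(risk = data.frame(sample_id = survival$sample_id, risk = risk,
                         group = group, stringsAsFactors = FALSE),
       fold_selected = fold_selected)
}

#' Consensus feature selection across outer folds
#'
#' @param per_fold_sets List of character vectors of selected feature labels.
#' @param frequency_threshold Minimum fraction of folds a feature must
#'   appear in (default 0.5).
#' @return Character vector of consensus-selected labels.
#' @export
consensus_selection <- function(per_fold_sets, frequency_threshold = 0.5) {
  if (length(per_fold_sets) == 0L) stop("empty fold list", call. = FALSE)
  freq <- table(unlist(per_fold_sets)) / length(per_fold_sets)
  sort(as.character(names(freq)[freq >= frequency_threshold]))
}

#' Dichotomize risk indices at a threshold
#'
#' Risk less than or equal to the threshold goes to the low group, strictly
#' greater to the high group (ties at the threshold are low).
#'
#' @param risks Numeric vector of risk indices.
#' @param threshold Split point (typically the training median risk).
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(risks, threshold) {
  if (any(!is.finite(risks))) stop("non-finite risk indices", call. = FALSE)
  if (length(risks) > 1L && length(unique(risks)) == 1L)
    warning("all risk indices identical: single-group split")
  factor(ifelse(risks > threshold, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator: at each distinct event time with `d` events
#' among `n` at risk, survival multiplies by `(1 - d/n)`; censored times
#' only reduce the risk set.
#'
#' @param survival Data frame with columns `time` and `event`.
#' @return List with `time`, `n_risk`, `n_event`, `surv` (values at the
#'   distinct observed times), `step` (right-continuous step function
#'   `time -> survival probability`) and the underlying `survfit` object.
#' @export
km_estimate <- function(survival) {
  if (nrow(survival) < 1) stop("need at least one record", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = survival)
  list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
       surv = fit$surv,
       step = stats::stepfun(fit$time, c(1, fit$surv)),
       fit = fit)
}

#' Log-rank test for survival differences between groups
#'
#' Standard g-sample log-rank test: observed minus expected event counts per
#' group across pooled event times with hypergeometric variance, compared to
#' a chi-square distribution on g - 1 degrees of freedom.
#'
#' @param survival Data frame with columns `time` and `event`.
#' @param groups Group labels, one per row of `survival` (>= 2 levels).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(survival, groups) {
  groups <- as.factor(as.character(groups))
  g <- nlevels(droplevels(groups))
  if (g < 2) stop("log-rank test needs at least 2 non-empty groups", call. = FALSE)
  if (sum(survival$event) < 1) stop("log-rank test needs at least one event", call. = FALSE)
  d <- data.frame(time = survival$time, event = survival$event,
                  g = droplevels(groups))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  df <- g - 1
  list(statistic = as.numeric(sd_$chisq), df = df,
       p_value = stats::pchisq(as.numeric(sd_$chisq), df = df, lower.tail = FALSE))
}
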