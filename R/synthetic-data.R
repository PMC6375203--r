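#' Configure a synthetic two-platform cohort
#'
#' Builds and validates the configuration for [generate_cohort()]. Each module
#' specification is a list with elements `size` (number of genes, >= 2) and
#' `cor` (target within-module pairwise correlation, in (0, 1]). Shared
#' modules are planted with the same latent factor on both platforms;
#' platform-unique modules are planted on one platform while the same gene
#' symbols are independent background noise on the other.
#'
#' @param n_samples Number of patients.
#' @param n_genes_per_platform Number of genes (rows) on each platform.
#' @param shared_modules,unique_modules_platform1,unique_modules_platform2
#'   Named lists of module specifications (see Details). Unnamed entries are
#'   auto-labelled `S*`, `U1_*`, `U2_*`.
#' @param hazard_coefficients Named numeric vector mapping planted-module
#'   labels to Cox log-hazard coefficients; omitted modules get beta = 0.
#' @param baseline_hazard Exponential baseline hazard rate (events per month).
#' @param censoring_rate_target Desired fraction of censored patients, in
#'   `[0, 1)`; 0 disables censoring.
#' @param noise_sd Per-gene noise standard deviation; `NULL` (default)
#'   calibrates it per module from the correlation target so a gene pair at
#'   the mean loading attains the target correlation.
#' @param subgroup_probs Optional mixing proportions of latent patient
#'   subgroups (molecular subtypes). When given, a module specification may
#'   carry a `subgroup_shift` vector (one value per subgroup) added to the
#'   mean of that module's latent factor, so subtypes coordinately activate
#'   modules. Default `NULL`: factors are standard normal for everyone.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 200L,
                          n_genes_per_platform = 500L,
                          shared_modules = list(),
                          unique_modules_platform1 = list(),
                          unique_modules_platform2 = list(),
                          hazard_coefficients = numeric(),
                          baseline_hazard = 0.05,
                          censoring_rate_target = 0.3,
                          noise_sd = NULL,
                          subgroup_probs = NULL,
                          seed = 1L) {
  label_specs <- function(specs, prefix) {
    if (length(specs) == 0L) return(specs)
    nm <- names(specs)
    if (is.null(nm)) nm <- rep("", length(specs))
    auto <- sprintf("%s%d", prefix, seq_along(specs))
    names(specs) <- ifelse(nm == "", auto, nm)
    specs
  }
  shared_modules <- label_specs(shared_modules, "S")
  unique_modules_platform1 <- label_specs(unique_modules_platform1, "U1_")
  unique_modules_platform2 <- label_specs(unique_modules_platform2, "U2_")
  all_specs <- c(shared_modules, unique_modules_platform1, unique_modules_platform2)
  for (lab in names(all_specs)) {
    sp <- all_specs[[lab]]
    if (is.null(sp$size) || sp$size < 2)
      stop("module '", lab, "': size must be >= 2", call. = FALSE)
    if (is.null(sp$cor) || sp$cor <= 0 || sp$cor > 1)
      stop("module '", lab, "': correlation target must be in (0, 1]", call. = FALSE)
    if (!is.null(sp$subgroup_shift)) {
      if (is.null(subgroup_probs))
        stop("module '", lab, "': subgroup_shift given without subgroup_probs",
             call. = FALSE)
      if (length(sp$subgroup_shift) != length(subgroup_probs))
        stop("module '", lab, "': subgroup_shift length must match subgroup_probs",
             call. = FALSE)
    }
  }
  if (!is.null(subgroup_probs)) {
    if (any(subgroup_probs <= 0) || abs(sum(subgroup_probs) - 1) > 1e-8)
      stop("subgroup_probs must be positive and sum to 1", call. = FALSE)
  }
  if (anyDuplicated(names(all_specs)))
    stop("module labels must be unique across all module lists", call. = FALSE)
  sizes <- vapply(all_specs, function(s) as.integer(s$size), integer(1))
  size1 <- sum(sizes[names(shared_modules)]) + sum(sizes[names(unique_modules_platform1)])
  size2 <- sum(sizes[names(shared_modules)]) + sum(sizes[names(unique_modules_platform2)])
  if (size1 > n_genes_per_platform || size2 > n_genes_per_platform || sum(sizes) > n_genes_per_platform)
    stop("infeasible config: planted module sizes exceed n_genes_per_platform", call. = FALSE)
  if (censoring_rate_target < 0 || censoring_rate_target >= 1)
    stop("censoring_rate_target must be in [0, 1)", call. = FALSE)
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive", call. = FALSE)
  if (!is.null(noise_sd) && noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  unknown <- setdiff(names(hazard_coefficients), names(all_specs))
  if (length(unknown))
    stop("hazard_coefficients refer to unknown modules: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(
    n_samples = as.integer(n_samples),
    n_genes_per_platform = as.integer(n_genes_per_platform),
    shared_modules = shared_modules,
    unique_modules_platform1 = unique_modules_platform1,
    unique_modules_platform2 = unique_modules_platform2,
    hazard_coefficients = hazard_coefficients,
    baseline_hazard = baseline_hazard,
    censoring_rate_target = censoring_rate_target,
    noise_sd = noise_sd,
    subgroup_probs = subgroup_probs,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Draw survival times from an exponential proportional-hazards model
#'
#' Event times are exponential with rate `baseline_hazard * exp(eta)`.
#' Censoring times are Uniform(0, u) with `u` calibrated by root-finding so
#' the expected censoring fraction, given the drawn event times, matches
#' `censoring_rate_target`. Uses the current RNG state.
#'
#' @param eta Linear predictor (one value per patient).
#' @param baseline_hazard Positive baseline rate.
#' @param censoring_rate_target Fraction in `[0, 1)`; 0 means no censoring.
#' @param sample_ids Optional patient identifiers.
#' @return A data.frame with columns `sample_id`, `time`, `event`, `group`.
#' @export
survival_from_linpred <- function(eta, baseline_hazard = 0.05,
                                  censoring_rate_target = 0.3,
                                  sample_ids = names(eta)) {
  n <- length(eta)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  t_event <- stats::rexp(n, rate = baseline_hazard * exp(eta))
  if (censoring_rate_target > 0) {
    # E[censored | T] for C ~ U(0, u) is mean(pmin(T/u, 1)); solve for u
    f <- function(u) mean(pmin(t_event / u, 1)) - censoring_rate_target
    u <- stats::uniroot(f, lower = min(t_event) * 1e-6,
                        upper = max(t_event) / censoring_rate_target * 1e3,
                        tol = 1e-10)$root
    t_cens <- stats::runif(n, 0, u)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  data.frame(sample_id = sample_ids, time = time, event = event,
             group = "all", stringsAsFactors = FALSE)
}

#' Generate a synthetic paired-platform cohort with planted modules
#'
#' Each planted module follows a single-latent-factor model: for gene g in
#' module m, `x_g = a_g * f_m + noise`, with loadings `a_g` drawn uniformly
#' from `[0.6, 1]` with random signs and `f_m ~ N(0, 1)` over patients.
#' Shared modules reuse the same factor on both platforms. Background genes
#' are independent standard normal noise. Survival follows an exponential
#' proportional-hazards model with linear predictor
#' `sum_m beta_m * f_m` and uniform censoring calibrated to the target rate.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: list with elements `expr1`,
#'   `expr2` (genes x samples matrices, `platform` attribute set), `survival`
#'   (data.frame), `truth` (planted memberships, factors, hazard betas) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_genes_per_platform
  samples <- sprintf("P%04d", seq_len(n))
  genes <- sprintf("G%05d", seq_len(p))

  specs <- c(config$shared_modules, config$unique_modules_platform1,
             config$unique_modules_platform2)
  labels <- names(specs)
  sizes <- vapply(specs, function(s) as.integer(s$size), integer(1))
  # disjoint gene blocks, allocated front-to-back
  offsets <- cumsum(c(0L, sizes))
  membership <- stats::setNames(lapply(seq_along(specs), function(i) {
    genes[(offsets[i] + 1L):(offsets[i] + sizes[i])]
  }), labels)

  subgroup <- if (!is.null(config$subgroup_probs)) {
    sample(seq_along(config$subgroup_probs), n, replace = TRUE,
           prob = config$subgroup_probs)
  } else rep(1L, n)
  factors <- matrix(stats::rnorm(n * length(specs)), nrow = n,
                    dimnames = list(samples, labels))
  for (lab in labels) {
    shift <- specs[[lab]]$subgroup_shift
    if (!is.null(shift)) factors[, lab] <- factors[, lab] + shift[subgroup]
  }

  plant <- function(platform_labels) {
    x <- matrix(stats::rnorm(p * n), nrow = p, dimnames = list(genes, samples))
    for (lab in platform_labels) {
      g <- membership[[lab]]
      k <- length(g)
      a <- stats::runif(k, 0.6, 1) * sample(c(-1, 1), k, replace = TRUE)
      sd_m <- if (is.null(config$noise_sd)) {
        0.8 * sqrt(1 / specs[[lab]]$cor - 1)  # mean loading 0.8 hits the target
      } else config$noise_sd
      x[g, ] <- outer(a, factors[, lab]) +
        matrix(stats::rnorm(k * n, sd = sd_m), nrow = k)
    }
    x
  }
  labels1 <- c(names(config$shared_modules), names(config$unique_modules_platform1))
  labels2 <- c(names(config$shared_modules), names(config$unique_modules_platform2))
  expr1 <- plant(labels1)
  expr2 <- plant(labels2)
  attr(expr1, "platform") <- "platform1"
  attr(expr2, "platform") <- "platform2"

  beta <- stats::setNames(numeric(length(labels)), labels)
  beta[names(config$hazard_coefficients)] <- config$hazard_coefficients
  eta <- as.numeric(factors %*% beta)
  surv <- survival_from_linpred(eta, config$baseline_hazard,
                                config$censoring_rate_target, samples)

  structure(list(
    expr1 = expr1,
    expr2 = expr2,
    survival = surv,
    truth = list(
      modules1 = membership[labels1],
      modules2 = membership[labels2],
      factors = factors,
      hazard_coefficients = beta,
      subgroup = stats::setNames(subgroup, samples)
    ),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic two-platform cohort\n")
  cat("  samples:", nrow(x$truth$factors),
      " genes/platform:", nrow(x$expr1), "\n")
  cat("  planted modules platform1:", paste(names(x$truth$modules1), collapse = ", "), "\n")
  cat("  planted modules platform2:", paste(names(x$truth$modules2), collapse = ", "), "\n")
  cat("  events:", sum(x$survival$event), "of", nrow(x$survival), "\n")
  invisible(x)
}

#' Jaccard overlap between truth modules and mined modules
#'
#' @param truth_modules Named list of gene-id character vectors.
#' @param found_modules List of mined modules (`gene_module` objects or
#'   character vectors of gene ids).
#' @return Matrix of Jaccard ratios, rows = truth modules, columns = found
#'   modules.
#' @export
truth_overlap <- function(truth_modules, found_modules) {
  found_sets <- lapply(found_modules, function(m) {
    if (is.list(m)) m$genes else m
  })
  if (any(vapply(truth_modules, length, integer(1)) == 0L) ||
      any(vapply(found_sets, length, integer(1)) == 0L))
    stop("empty module: Jaccard ratio undefined", call. = FALSE)
  out <- matrix(0, nrow = length(truth_modules), ncol = length(found_sets))
  rownames(out) <- names(truth_modules)
  colnames(out) <- vapply(seq_along(found_modules), function(j) {
    m <- found_modules[[j]]
    if (is.list(m) && !is.null(m$label)) m$label else as.character(j)
  }, character(1))
  for (i in seq_along(truth_modules)) {
    for (j in seq_along(found_sets)) {
      out[i, j] <- jaccard_index(truth_modules[[i]], found_sets[[j]])
    }
  }
  out
}
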