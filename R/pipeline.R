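#' Read an expression matrix from tab-separated text
#'
#' Expected layout: header row of sample ids, first column of gene symbols,
#' tab-separated numeric values.
#'
#' @param path File path.
#' @param platform Optional platform tag stored as an attribute.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path, platform = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(d[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene symbol(s): ", paste(dup, collapse = ", "), call. = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- genes
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression file contains missing values", call. = FALSE)
  if (!is.null(platform)) attr(m, "platform") <- platform
  m
}

#' Write an expression matrix as tab-separated text
#'
#' @param expr Genes x samples matrix.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table (sample id, survival time, event, group)
#'
#' Validates that times are positive and the event indicator is 0/1.
#'
#' @param path File path to a tab-separated table with a header containing
#'   at least `sample_id`, `time`, `event` (optional `group`).
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(d)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  bad_t <- which(!is.finite(d$time) | d$time <= 0)
  if (length(bad_t))
    stop("non-positive survival time at row(s): ",
         paste(utils::head(bad_t, 5), collapse = ", "), call. = FALSE)
  bad_e <- which(!d$event %in% c(0, 1))
  if (length(bad_e))
    stop("event indicator must be 0 or 1; offending row(s): ",
         paste(utils::head(bad_e, 5), collapse = ", "), call. = FALSE)
  if (is.null(d$group)) d$group <- "all"
  d
}

#' Write a clinical table
#' @param survival Data frame with `sample_id`, `time`, `event` (and
#'   optionally `group`).
#' @param path Output path.
#' @export
write_clinical <- function(survival, path) {
  utils::write.table(survival, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene modules in GMT format
#'
#' One line per module: label, description (platform), then tab-separated
#' gene symbols.
#'
#' @param modules `gene_module_list` or list of gene-id vectors.
#' @param path Output path.
#' @export
write_modules_gmt <- function(modules, path) {
  lines <- vapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    if (is.list(m)) {
      paste(c(m$label, m$platform, m$genes), collapse = "\t")
    } else {
      paste(c(sprintf("M%d", i), "na", m), collapse = "\t")
    }
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene modules from a GMT file
#' @param path File path.
#' @return `gene_module_list`.
#' @export
read_modules_gmt <- function(path) {
  lines <- readLines(path)
  mods <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    structure(list(label = f[1], genes = f[-(1:2)], platform = f[2],
                   size = length(f) - 2L, density = NA_real_),
              class = "gene_module")
  })
  structure(mods, class = "gene_module_list")
}

#' Write a results bundle report as JSON
#'
#' Serializes the scalar/tabular parts of a [run_pipeline()] bundle
#' (module sizes, uniqueness table, selected features, survival tests,
#' provenance).
#'
#' @param bundle Result of [run_pipeline()].
#' @param path Output path.
#' @export
write_report <- function(bundle, path) {
  rep <- list(
    modules_platform1 = lapply(bundle$modules1, function(m)
      list(label = m$label, size = m$size, density = m$density)),
    modules_platform2 = lapply(bundle$modules2, function(m)
      list(label = m$label, size = m$size, density = m$density)),
    uniqueness = bundle$uniqueness,
    coherence = bundle$coherence,
    selected_platform1 = bundle$selected1,
    selected_platform2 = bundle$selected2,
    fusion_features = bundle$fusion_features,
    survival_tests = bundle$survival_tests,
    provenance = bundle$provenance
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full integrative survival-prognosis workflow
#'
#' Orchestrates, in order: module mining per platform (lmQCM on the absolute
#' Spearman network), eigengene summarization, cross-platform uniqueness and
#' coherence statistics, lasso-Cox selection of survival-associated
#' eigengenes per platform, assembly of the fusion feature set (selected
#' eigengenes, de-duplicating cross-platform counterpart pairs by keeping
#' the module with the higher Correlation Index), per-platform spectral
#' clustering on all and on selected eigengenes, Similarity Network Fusion
#' of the two per-platform patient networks built from the fusion features,
#' spectral clustering of the fused network, and a log-rank survival test
#' for every clustering.
#'
#' @param expr1,expr2 Genes x samples matrices for the two platforms over
#'   the same samples.
#' @param survival Clinical data frame (`sample_id`, `time`, `event`).
#' @param lmqcm [lmqcm_params()] used for both platforms.
#' @param normalize If `TRUE`, mine the spectrally normalized weight matrix
#'   (the seed threshold is then rescaled to `gamma * max` weight); default
#'   mines the raw absolute-Spearman matrix, on whose `[0, 1]` scale the
#'   default `gamma = 0.80` is calibrated.
#' @param jaccard_threshold,fisher_threshold Uniqueness thresholds.
#' @param coherence_n_perm Permutation draws for the Correlation Index
#'   p-value (0 disables the permutation test).
#' @param selection `"full"` (one lasso-Cox fit per platform, default) or
#'   `"loocv"` (leave-one-out consensus selection).
#' @param consensus_threshold Fold-frequency threshold for `"loocv"`.
#' @param inner_folds Inner CV folds for the penalty choice.
#' @param penalty `"min"` or `"1se"` penalty rule.
#' @param snf_K,snf_mu,snf_iters SNF neighbor count, kernel scale and
#'   iteration count.
#' @param n_clusters Number of spectral clusters for every stratification.
#' @param dedupe_fusion Drop the lower-coherence member of cross-platform
#'   selected module pairs that are not mutually unique (default `TRUE`).
#' @param seed Global integer seed; the bundle is a pure function of the
#'   inputs and this seed.
#' @return A list bundle: mined modules, eigengene matrices, uniqueness and
#'   coherence tables, selected features, fusion features, risk models,
#'   cluster labels and log-rank reports, plus provenance.
#' @export
run_pipeline <- function(expr1, expr2, survival,
                         lmqcm = lmqcm_params(),
                         normalize = FALSE,
                         jaccard_threshold = 0.05, fisher_threshold = 0.05,
                         coherence_n_perm = 0L,
                         selection = c("full", "loocv"),
                         consensus_threshold = 0.5,
                         inner_folds = 10L,
                         penalty = c("min", "1se"),
                         snf_K = 30L, snf_mu = 0.8, snf_iters = 20L,
                         n_clusters = 3L,
                         dedupe_fusion = TRUE,
                         seed = 1L) {
  selection <- match.arg(selection)
  penalty <- match.arg(penalty)
  ids <- survival$sample_id
  if (!setequal(colnames(expr1), colnames(expr2)) || !setequal(colnames(expr1), ids)) {
    bad <- c(setdiff(ids, colnames(expr1)), setdiff(colnames(expr1), ids),
             setdiff(colnames(expr1), colnames(expr2)))
    stop("sample-id mismatch between inputs: ",
         paste(utils::head(unique(bad), 5), collapse = ", "), call. = FALSE)
  }
  expr1 <- expr1[, ids, drop = FALSE]
  expr2 <- expr2[, ids, drop = FALSE]

  mine_one <- function(expr, prefix, platform) {
    W <- spearman_weight_matrix(expr)
    if (normalize) W <- normalize_weights(W)
    lmqcm_mine(W, lmqcm, label_prefix = prefix, platform = platform,
               scale_gamma = normalize)
  }
  mods1 <- mine_one(expr1, "M", "platform1")
  mods2 <- mine_one(expr2, "R", "platform2")
  if (length(mods1) == 0L || length(mods2) == 0L)
    stop("mining stage produced no modules on platform ",
         if (length(mods1) == 0L) "1" else "2", call. = FALSE)

  eig1 <- eigengene_matrix(expr1, mods1)
  eig2 <- eigengene_matrix(expr2, mods2)

  universe <- intersect(rownames(expr1), rownames(expr2))
  uniq <- unique_modules(mods1, mods2, universe,
                         jaccard_threshold, fisher_threshold)

  coh_one <- function(expr, mods, platform) {
    do.call(rbind, lapply(mods, function(m) {
      C <- correlation_index(module_scc_matrix(expr, m$genes))
      p <- if (coherence_n_perm > 0)
        correlation_index_p(expr, m, n_perm = coherence_n_perm, seed = seed)$p
      else NA_real_
      data.frame(module_label = m$label, platform = platform, K = m$size,
                 C = C, p = p, stringsAsFactors = FALSE)
    }))
  }
  coherence <- rbind(coh_one(expr1, mods1, "platform1"),
                     coh_one(expr2, mods2, "platform2"))

  select_one <- function(eig, seed_off) {
    if (selection == "full") {
      fit <- lasso_cox_fit(eig, survival, inner_folds = inner_folds,
                           seed = seed + seed_off, penalty = penalty)
      list(selected = fit$selected_features, model = fit, fold_selected = NULL)
    } else {
      cv <- loocv_risk_indices(eig, survival, inner_folds = inner_folds,
                               seed = seed + seed_off, penalty = penalty)
      list(selected = consensus_selection(cv$fold_selected, consensus_threshold),
           model = cv, fold_selected = cv$fold_selected)
    }
  }
  sel1 <- select_one(eig1, 101L)
  sel2 <- select_one(eig2, 202L)

  # fusion feature set: selected eigengenes, de-duplicating cross-platform
  # counterpart pairs (not mutually unique) by the higher Correlation Index
  fus1 <- sel1$selected
  fus2 <- sel2$selected
  if (dedupe_fusion && length(fus1) && length(fus2)) {
    label_genes <- function(mods) stats::setNames(lapply(mods, `[[`, "genes"),
                                                  vapply(mods, `[[`, "", "label"))
    g1 <- label_genes(mods1)
    g2 <- label_genes(mods2)
    getC <- function(lab) coherence$C[coherence$module_label == lab]
    for (a in sel1$selected) {
      for (b in sel2$selected) {
        jac <- jaccard_index(g1[[a]], g2[[b]])
        fis <- overlap_fisher_p(g1[[a]], g2[[b]], universe)
        if (jac >= jaccard_threshold || fis <= fisher_threshold) {
          if (getC(a) >= getC(b)) fus2 <- setdiff(fus2, b)
          else fus1 <- setdiff(fus1, a)
        }
      }
    }
  }
  fallback <- FALSE
  if (length(fus1) == 0L) {
    warning("no platform-1 fusion features survive selection; using all its eigengenes")
    fus1 <- rownames(eig1)
    fallback <- TRUE
  }
  if (length(fus2) == 0L) {
    warning("no platform-2 fusion features survive selection; using all its eigengenes")
    fus2 <- rownames(eig2)
    fallback <- TRUE
  }

  cluster_and_test <- function(features, what) {
    if (is.null(features) || nrow(features) == 0L) return(NULL)
    W <- affinity_kernel(features, K = snf_K, mu = snf_mu)
    cl <- spectral_cluster(W, n_clusters, seed = seed)
    lt <- logrank_test(survival, cl[survival$sample_id])
    list(what = what, labels = cl, statistic = lt$statistic, df = lt$df,
         p_value = lt$p_value)
  }
  res_all1 <- cluster_and_test(eig1, "platform1_all")
  res_all2 <- cluster_and_test(eig2, "platform2_all")
  res_sel1 <- cluster_and_test(eig1[sel1$selected, , drop = FALSE], "platform1_selected")
  res_sel2 <- cluster_and_test(eig2[sel2$selected, , drop = FALSE], "platform2_selected")

  fused <- NULL
  res_fused <- NULL
  f1 <- eig1[fus1, , drop = FALSE]
  f2 <- eig2[fus2, , drop = FALSE]
  if (nrow(f1) > 0L && nrow(f2) > 0L) {
    A1 <- affinity_kernel(f1, K = snf_K, mu = snf_mu)
    A2 <- affinity_kernel(f2, K = snf_K, mu = snf_mu)
    fused <- snf_fuse(A1, A2, K = min(snf_K, nrow(A1) - 1L), iters = snf_iters)
    cl <- spectral_cluster(fused, n_clusters, seed = seed)
    lt <- logrank_test(survival, cl[survival$sample_id])
    res_fused <- list(what = "snf_fused", labels = cl,
                      statistic = lt$statistic, df = lt$df, p_value = lt$p_value)
  } else {
    warning("fusion skipped: one platform contributes no features")
  }

  tests <- Filter(Negate(is.null),
                  list(res_all1, res_sel1, res_all2, res_sel2, res_fused))
  names(tests) <- vapply(tests, `[[`, "", "what")

  list(
    modules1 = mods1, modules2 = mods2,
    eigengenes1 = eig1, eigengenes2 = eig2,
    uniqueness = uniq, coherence = coherence,
    selected1 = sel1$selected, selected2 = sel2$selected,
    model1 = sel1$model, model2 = sel2$model,
    fusion_features = list(platform1 = fus1, platform2 = fus2,
                           fallback_all = fallback),
    fused_matrix = fused,
    survival_tests = lapply(tests, function(t_) t_[c("what", "statistic", "df", "p_value")]),
    cluster_labels = lapply(tests, `[[`, "labels"),
    provenance = list(
      seed = seed, normalize = normalize, lmqcm = unclass(lmqcm),
      jaccard_threshold = jaccard_threshold, fisher_threshold = fisher_threshold,
      selection = selection, penalty = penalty, inner_folds = inner_folds,
      consensus_threshold = consensus_threshold,
      snf = list(K = snf_K, mu = snf_mu, iters = snf_iters),
      n_clusters = n_clusters,
      package_version = as.character(utils::packageVersion("gcnfuse"))
    )
  )
}
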