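# Independent brute-force oracles, deliberately naive: everything is
# recomputed from scratch with explicit loops so that agreement with the
# package's vectorized implementations is meaningful.

# density of a vertex set by direct double loop
oracle_density <- function(W, members) {
  s <- 0
  k <- length(members)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) s <- s + W[members[a], members[b]]
  }
  2 * s / (k * (k - 1))
}

# seed edges: weight >= gamma and no heavier edge shares an endpoint;
# descending weight, ties by lexicographically smallest gene pair
oracle_seeds <- function(W, gamma) {
  ids <- sort(rownames(W))
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      w <- W[ids[i], ids[j]]
      if (w < gamma) next
      ok <- TRUE
      for (k in seq_along(ids)) {
        if (ids[k] != ids[i] && W[ids[i], ids[k]] > w) ok <- FALSE
        if (ids[k] != ids[j] && W[ids[j], ids[k]] > w) ok <- FALSE
      }
      if (ok) out[[length(out) + 1]] <- list(g1 = ids[i], g2 = ids[j], w = w)
    }
  }
  if (!length(out)) return(data.frame(gene1 = character(), gene2 = character(),
                                      weight = numeric()))
  d <- do.call(rbind, lapply(out, function(e)
    data.frame(gene1 = e$g1, gene2 = e$g2, weight = e$w,
               stringsAsFactors = FALSE)))
  d[order(-d$weight, d$gene1, d$gene2), , drop = FALSE]
}

# greedy growth simulated literally: each step, scan every outside vertex,
# compute its total weight to the members, take the best (lexicographic
# tie-break), accept while the enlarged density stays above the adaptive
# fraction of the current density
oracle_grow <- function(W, g1, g2, alpha, t) {
  ids <- sort(rownames(W))
  members <- c(g1, g2)
  repeat {
    outside <- setdiff(ids, members)
    if (!length(outside)) break
    gains <- sapply(outside, function(v) sum(W[v, members]))
    best <- outside[order(-gains, outside)][1]
    k <- length(members)
    d_cur <- oracle_density(W, members)
    d_new <- oracle_density(W, c(members, best))
    if (d_new < (1 - 1 / (2 * alpha * (k + 1 + t))) * d_cur) break
    members <- c(members, best)
  }
  sort(members)
}

# full mining pipeline: seeds -> growth -> size filter -> overlap merge to a
# fixed point (largest first) -> size-ranked gene sets
oracle_lmqcm <- function(W, gamma, alpha, t, beta, min_size) {
  sds <- oracle_seeds(W, gamma)
  sets <- list()
  for (s in seq_len(nrow(sds))) {
    m <- oracle_grow(W, sds$gene1[s], sds$gene2[s], alpha, t)
    if (length(m) >= min_size) sets[[length(sets) + 1]] <- m
  }
  sets <- unique(sets)
  repeat {
    if (length(sets) < 2) break
    o <- order(-sapply(sets, length), sapply(sets, function(g) g[1]))
    sets <- sets[o]
    merged <- FALSE
    for (a in seq_len(length(sets) - 1)) {
      for (b in (a + 1):length(sets)) {
        ov <- length(intersect(sets[[a]], sets[[b]])) /
          min(length(sets[[a]]), length(sets[[b]]))
        if (ov >= beta) {
          sets[[a]] <- sort(union(sets[[a]], sets[[b]]))
          sets <- sets[-b]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  if (!length(sets)) return(list())
  o <- order(-sapply(sets, length), sapply(sets, function(g) g[1]))
  sets[o]
}

# random symmetric weight matrix with labelled genes
random_weight_matrix <- function(n, labels = sprintf("g%02d", seq_len(n))) {
  W <- matrix(0, n, n, dimnames = list(labels, labels))
  W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2)
  W + t(W)
}

# plain (unadjusted) Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / (n * (n - 1) / 2)
}

# two-group log-rank statistic by direct O - E / hypergeometric-variance
# enumeration over pooled event times
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.character(group)
  gl <- sort(unique(group))
  stopifnot(length(gl) == 2)
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (tk in ts) {
    at_risk <- time >= tk
    n_k <- sum(at_risk)
    n1 <- sum(at_risk & group == gl[1])
    d_k <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & group == gl[1])
    O1 <- O1 + d1
    E1 <- E1 + d_k * n1 / n_k
    if (n_k > 1)
      V <- V + d_k * (n1 / n_k) * (1 - n1 / n_k) * (n_k - d_k) / (n_k - 1)
  }
  (O1 - E1)^2 / V
}

# One replicate of the integration-benefit experiment: a cohort whose
# survival signal is split across two platform-unique modules, each
# activated in a different patient subtype. Returns log-rank p-values for
# spectral clusterings on all eigengenes, selected eigengenes (per
# platform), and the SNF-fused network built from the selected+unique sets.
benefit_replicate <- function(seed, n = 150, p = 300, n_clusters = 3) {
  co <- generate_cohort(cohort_config(
    n_samples = n, n_genes_per_platform = p,
    shared_modules = list(S1 = list(size = 40, cor = 0.8),
                          S2 = list(size = 30, cor = 0.8)),
    unique_modules_platform1 = list(
      U1 = list(size = 25, cor = 0.8, subgroup_shift = c(0, 1.2, 0))),
    unique_modules_platform2 = list(
      U2 = list(size = 25, cor = 0.8, subgroup_shift = c(0, 0, 1.2))),
    hazard_coefficients = c(U1 = 0.7, U2 = 0.7),
    censoring_rate_target = 0.3,
    subgroup_probs = c(0.5, 0.25, 0.25),
    seed = seed))
  mods1 <- lmqcm_mine(spearman_weight_matrix(co$expr1), lmqcm_params(),
                      label_prefix = "M")
  mods2 <- lmqcm_mine(spearman_weight_matrix(co$expr2), lmqcm_params(),
                      label_prefix = "R")
  eig1 <- eigengene_matrix(co$expr1, mods1)
  eig2 <- eigengene_matrix(co$expr2, mods2)
  sel1 <- lasso_cox_fit(eig1, co$survival, seed = seed + 1)$selected_features
  sel2 <- lasso_cox_fit(eig2, co$survival, seed = seed + 2)$selected_features
  if (!length(sel1)) sel1 <- rownames(eig1)
  if (!length(sel2)) sel2 <- rownames(eig2)
  uniq <- unique_modules(mods1, mods2,
                         intersect(rownames(co$expr1), rownames(co$expr2)))
  u1 <- uniq$module_label[uniq$platform == "platform1" & uniq$unique]
  u2 <- uniq$module_label[uniq$platform == "platform2" & uniq$unique]
  fus1 <- intersect(sel1, u1); if (!length(fus1)) fus1 <- sel1
  fus2 <- intersect(sel2, u2); if (!length(fus2)) fus2 <- sel2
  pclust <- function(feats) {
    W <- affinity_kernel(feats, K = 30, mu = 0.8)
    cl <- spectral_cluster(W, n_clusters, seed = seed)
    logrank_test(co$survival, cl[co$survival$sample_id])$p_value
  }
  A1 <- affinity_kernel(eig1[fus1, , drop = FALSE], K = 30, mu = 0.8)
  A2 <- affinity_kernel(eig2[fus2, , drop = FALSE], K = 30, mu = 0.8)
  fused <- snf_fuse(A1, A2, K = 30, iters = 20)
  clf <- spectral_cluster(fused, n_clusters, seed = seed)
  c(p_all1 = pclust(eig1),
    p_sel1 = pclust(eig1[sel1, , drop = FALSE]),
    p_all2 = pclust(eig2),
    p_sel2 = pclust(eig2[sel2, , drop = FALSE]),
    p_fused = logrank_test(co$survival, clf[co$survival$sample_id])$p_value)
}

# small planted two-platform cohort used across tests
small_cohort <- function(seed = 101, n = 150, p = 250,
                         shared = list(S1 = list(size = 25, cor = 0.8),
                                       S2 = list(size = 20, cor = 0.8)),
                         u1 = list(U1 = list(size = 20, cor = 0.8)),
                         u2 = list(U2 = list(size = 20, cor = 0.8)),
                         beta = c(U1 = 1, U2 = 1),
                         censoring = 0.25) {
  if (is.null(beta)) beta <- numeric()
  generate_cohort(cohort_config(
    n_samples = n, n_genes_per_platform = p,
    shared_modules = shared,
    unique_modules_platform1 = u1,
    unique_modules_platform2 = u2,
    hazard_coefficients = beta,
    censoring_rate_target = censoring,
    seed = seed
  ))
}
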