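#' Jaccard index of two gene sets
#'
#' @param A,B Character vectors (at least one non-empty).
#' @return `|A ∩ B| / |A ∪ B|`.
#' @export
jaccard_index <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0 && length(B) == 0)
    stop("Jaccard index undefined for two empty sets", call. = FALSE)
  length(intersect(A, B)) / length(union(A, B))
}

#' One-sided Fisher exact (hypergeometric) overlap p-value
#'
#' Probability of observing at least the realized overlap between two gene
#' sets drawn from a common universe: the enrichment tail of the
#' hypergeometric distribution.
#'
#' @param A,B Gene sets, both subsets of `universe`.
#' @param universe Character vector of all genes considered.
#' @return p-value in `[0, 1]`.
#' @export
overlap_fisher_p <- function(A, B, universe) {
  A <- unique(A); B <- unique(B); universe <- unique(universe)
  if (length(setdiff(A, universe)) || length(setdiff(B, universe)))
    stop("gene set not contained in universe", call. = FALSE)
  ov <- length(intersect(A, B))
  stats::phyper(ov - 1, length(A), length(universe) - length(A), length(B),
                lower.tail = FALSE)
}

#' Cross-platform module uniqueness
#'
#' A module is unique to its platform iff, against EVERY module of the other
#' platform, the Jaccard index is below `jaccard_threshold` AND the Fisher
#' overlap p-value is above `fisher_threshold`. For each module the
#' worst-case partner (largest Jaccard) and the smallest Fisher p are
#' recorded.
#'
#' @param mods1,mods2 `gene_module_list`s (or lists of gene-id vectors) for
#'   the two platforms.
#' @param universe Genes present on both platforms.
#' @param jaccard_threshold,fisher_threshold Uniqueness thresholds
#'   (defaults 0.05 / 0.05).
#' @return Data frame with one row per module of both platforms: columns
#'   `module_label`, `platform`, `size`, `best_jaccard`, `best_fisher_p`,
#'   `partner_label`, `unique`.
#' @export
unique_modules <- function(mods1, mods2, universe,
                           jaccard_threshold = 0.05, fisher_threshold = 0.05) {
  get_genes <- function(m) if (is.list(m)) m$genes else m
  get_label <- function(m, i, pre) {
    if (is.list(m) && !is.null(m$label)) m$label else sprintf("%s%d", pre, i)
  }
  one_side <- function(mods, others, platform, pre, opre) {
    if (length(others) == 0L) {
      warning("no opposing modules on the other platform: all modules unique")
    }
    rows <- lapply(seq_along(mods), function(i) {
      g <- get_genes(mods[[i]])
      if (length(others)) {
        jac <- vapply(others, function(o) jaccard_index(g, get_genes(o)), numeric(1))
        fis <- vapply(others, function(o) overlap_fisher_p(g, get_genes(o), universe), numeric(1))
        best <- which.max(jac)
        data.frame(module_label = get_label(mods[[i]], i, pre),
                   platform = platform, size = length(g),
                   best_jaccard = jac[best], best_fisher_p = min(fis),
                   partner_label = get_label(others[[best]], best, opre),
                   unique = all(jac < jaccard_threshold) && all(fis > fisher_threshold),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(module_label = get_label(mods[[i]], i, pre),
                   platform = platform, size = length(g),
                   best_jaccard = 0, best_fisher_p = 1,
                   partner_label = NA_character_, unique = TRUE,
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  }
  rbind(one_side(mods1, mods2, "platform1", "M", "R"),
        one_side(mods2, mods1, "platform2", "R", "M"))
}

#' Correlation Index of a module
#'
#' For a module of K genes with absolute-correlation matrix `W_sub` (unit
#' diagonal), the Correlation Index is the squared Frobenius norm of
#' `W_sub - I` divided by `K^2`:
#' `C = || W_sub - I ||_F^2 / K^2`.
#'
#' @param W_sub Square K x K matrix of absolute Spearman correlations with
#'   unit diagonal.
#' @return Nonnegative scalar.
#' @export
correlation_index <- function(W_sub) {
  if (!is.matrix(W_sub) || nrow(W_sub) != ncol(W_sub))
    stop("W_sub must be a square matrix", call. = FALSE)
  K <- nrow(W_sub)
  sum((W_sub - diag(K))^2) / K^2
}

# Absolute Spearman correlation submatrix (unit diagonal) of a gene set.
module_scc_matrix <- function(expr, genes) {
  W <- abs(stats::cor(t(expr[genes, , drop = FALSE]), method = "spearman"))
  diag(W) <- 1
  W
}

#' Correlation Index with permutation p-value
#'
#' Computes the module's Correlation Index C and a permutation p-value:
#' `n_perm` random gene sets of the same size K are drawn uniformly without
#' replacement from all genes of the matrix, C* is computed for each, and
#' `p = #(C* > C) / n_perm` (strict inequality).
#'
#' @param expr Numeric matrix, genes x samples.
#' @param module `gene_module` or character vector of gene ids.
#' @param n_perm Number of random draws (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `coherence_result`: `C`, `p`, `K`, `n_perm`.
#' @export
correlation_index_p <- function(expr, module, n_perm = 1000L, seed = NULL) {
  genes <- if (is.list(module)) module$genes else module
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("module gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  K <- length(genes)
  if (nrow(expr) < 2 * K)
    stop("fewer than K other genes available for the permutation null", call. = FALSE)
  C <- correlation_index(module_scc_matrix(expr, genes))
  if (!is.null(seed)) set.seed(seed)
  all_genes <- rownames(expr)
  c_star <- vapply(seq_len(n_perm), function(i) {
    correlation_index(module_scc_matrix(expr, sample(all_genes, K)))
  }, numeric(1))
  structure(list(C = C, p = sum(c_star > C) / n_perm, K = K,
                 n_perm = as.integer(n_perm)),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("Correlation Index C = %.4f (K = %d), permutation p = %.4g (%d draws)\n",
              x$C, x$K, x$p, x$n_perm))
  invisible(x)
}

#' Train/test module coherence stability
#'
#' Evaluates the Correlation Index of a module on a training and a testing
#' sample split, together with the distribution of C over `n_random`
#' size-matched random gene sets evaluated on the testing split. A stable,
#' genuinely co-expressed module has `C_test` far in the upper tail of the
#' random-set distribution.
#'
#' @param expr_train,expr_test Genes x samples matrices over the same genes.
#' @param module `gene_module` or character vector of gene ids.
#' @param n_random Number of random gene sets (default 1000).
#' @param seed Optional integer seed.
#' @return List with `C_train`, `C_test`, `random_C` (numeric vector).
#' @export
module_stability <- function(expr_train, expr_test, module,
                             n_random = 1000L, seed = NULL) {
  genes <- if (is.list(module)) module$genes else module
  missing <- c(setdiff(genes, rownames(expr_train)), setdiff(genes, rownames(expr_test)))
  if (length(missing))
    stop("module gene(s) absent from a split: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  C_train <- correlation_index(module_scc_matrix(expr_train, genes))
  C_test <- correlation_index(module_scc_matrix(expr_test, genes))
  if (!is.null(seed)) set.seed(seed)
  all_genes <- rownames(expr_test)
  random_C <- vapply(seq_len(n_random), function(i) {
    correlation_index(module_scc_matrix(expr_test, sample(all_genes, length(genes))))
  }, numeric(1))
  list(C_train = C_train, C_test = C_test, random_C = random_C)
}
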