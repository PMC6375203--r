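#' Absolute Spearman correlation weight matrix
#'
#' Builds the weighted co-expression network: `W(i, j)` is the absolute
#' Spearman rank correlation between the expression profiles of genes i and
#' j across samples. The diagonal is forced to zero (self-edges are excluded
#' from mining). Genes with zero rank variance get all-zero weights, with a
#' warning.
#'
#' @param expr Numeric matrix, genes x samples, with gene ids as rownames.
#' @return Symmetric matrix in `[0, 1]` with attribute `normalized = FALSE`.
#' @export
spearman_weight_matrix <- function(expr) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 3) stop("need at least 3 samples for Spearman weights", call. = FALSE)
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids", call. = FALSE)
  if (anyNA(expr)) stop("expression matrix contains missing values", call. = FALSE)
  const <- apply(expr, 1, function(x) all(x == x[1]))
  W <- matrix(0, nrow(expr), nrow(expr), dimnames = list(rownames(expr), rownames(expr)))
  if (any(!const)) {
    Wv <- abs(stats::cor(t(expr[!const, , drop = FALSE]), method = "spearman"))
    W[!const, !const] <- Wv
  }
  if (any(const)) {
    warning("constant gene(s) with zero rank variance, weights set to 0: ",
            paste(utils::head(rownames(expr)[const], 5), collapse = ", "))
  }
  diag(W) <- 0
  attr(W, "normalized") <- FALSE
  W
}

#' Spectral (symmetric degree) normalization of a weight matrix
#'
#' `Wn(i, j) = W(i, j) / sqrt(d_i * d_j)` with `d_i = sum_k W(i, k)`, the
#' normalization adopted from spectral clustering. Isolated genes (zero
#' degree) keep all-zero rows/columns, with a warning. Note that this
#' rescales the weights, so a seed threshold meant for the raw `[0, 1]`
#' scale must be rescaled too (see [lmqcm_mine()]).
#'
#' @param W Symmetric nonnegative weight matrix (diagonal zero).
#' @return Normalized matrix with attribute `normalized = TRUE`.
#' @export
normalize_weights <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  d <- rowSums(W)
  iso <- d == 0
  if (any(iso)) {
    warning("isolated gene(s) with zero degree left at weight 0: ",
            paste(utils::head(rownames(W)[iso], 5), collapse = ", "))
    d[iso] <- 1  # rows are already all zero; avoid 0/0
  }
  s <- 1 / sqrt(d)
  Wn <- W * outer(s, s)
  dimnames(Wn) <- dimnames(W)
  attr(Wn, "normalized") <- TRUE
  Wn
}

#' Weighted density of a gene set
#'
#' `2 * sum_{i<j in members} W(i, j) / (|members| * (|members| - 1))`.
#'
#' @param W Weight matrix with zero diagonal.
#' @param members Indices or gene ids, at least 2.
#' @return Scalar density.
#' @export
weighted_density <- function(W, members) {
  if (length(members) < 2) stop("weighted density undefined for fewer than 2 genes", call. = FALSE)
  sub <- W[members, members, drop = FALSE]
  sum(sub) / (length(members) * (length(members) - 1))
}

#' lmQCM mining parameters
#'
#' `gamma` is the seed edge-weight threshold (the most important parameter:
#' it gates the initiation of a new cluster); `alpha` and `t` parameterize
#' the adaptive density criterion that stops the greedy growth; `beta` is
#' the overlap ratio above which two mined clusters are merged. Defaults are
#' gamma = 0.80, t = 1, alpha = 1, beta = 0.4, minimum module size 10.
#'
#' @param gamma Seed threshold in `(0, 1]` on the scale of the mined matrix.
#' @param t Density-offset count (>= 0).
#' @param alpha Density-scale (> 0).
#' @param beta Merge-overlap ratio in `(0, 1]`.
#' @param min_module_size Smallest module retained.
#' @return An object of class `lmqcm_params`.
#' @export
lmqcm_params <- function(gamma = 0.80, t = 1, alpha = 1, beta = 0.4,
                         min_module_size = 10L) {
  stopifnot(gamma > 0, gamma <= 1, beta > 0, beta <= 1, t >= 0, alpha > 0,
            min_module_size >= 2)
  structure(list(gamma = gamma, t = t, alpha = alpha, beta = beta,
                 min_module_size = as.integer(min_module_size)),
            class = "lmqcm_params")
}

#' Seed edges for lmQCM
#'
#' An edge (i, j) is a seed if its weight is at least `gamma` and is a local
#' maximum: no edge sharing either endpoint is heavier (i.e. the edge is the
#' row maximum for both endpoints). Returned in descending weight order,
#' ties broken by lexicographically smallest gene-id pair.
#'
#' @param W Symmetric weight matrix with zero diagonal and gene rownames.
#' @param gamma Seed threshold.
#' @return Data frame with columns `gene1`, `gene2`, `weight`.
#' @export
lmqcm_seeds <- function(W, gamma) {
  ids <- rownames(W)
  ord <- order(ids)
  W <- W[ord, ord]
  ids <- ids[ord]
  rmax <- apply(W, 1, max)
  idx <- which(upper.tri(W) & W >= gamma, arr.ind = TRUE)
  if (nrow(idx)) {
    keep <- W[idx] >= rmax[idx[, 1]] & W[idx] >= rmax[idx[, 2]]
    idx <- idx[keep, , drop = FALSE]
  }
  w <- W[idx]
  o <- order(-w, ids[idx[, 1]], ids[idx[, 2]])
  data.frame(gene1 = ids[idx[o, 1]], gene2 = ids[idx[o, 2]],
             weight = w[o], stringsAsFactors = FALSE)
}

# Greedy growth from one seed edge. Repeatedly adds the non-member vertex v*
# with the largest total weight to the current members S, accepting iff the
# enlarged set's weighted density satisfies
#   density(S + v*) >= (1 - 1/(2 * alpha * (|S| + 1 + t))) * density(S),
# the adaptive quasi-clique criterion (scale-invariant, so it applies
# unchanged to degree-normalized weights). Ties on the gain go to the
# lexicographically smallest gene id (indices are pre-sorted).
grow_from_seed <- function(W, i, j, alpha, t) {
  n <- nrow(W)
  in_set <- logical(n)
  in_set[c(i, j)] <- TRUE
  members <- c(i, j)
  gains <- W[i, ] + W[j, ]
  sum_w <- W[i, j]
  repeat {
    k <- length(members)
    g <- gains
    g[in_set] <- -Inf
    v <- which.max(g)
    dens_cur <- 2 * sum_w / (k * (k - 1))
    dens_new <- 2 * (sum_w + g[v]) / ((k + 1) * k)
    alpha_d <- 1 - 1 / (2 * alpha * (k + 1 + t))
    if (dens_new < alpha_d * dens_cur) break
    members <- c(members, v)
    in_set[v] <- TRUE
    sum_w <- sum_w + gains[v]
    gains <- gains + W[v, ]
  }
  members
}

#' Mine co-expressed gene modules with lmQCM
#'
#' Local maximum Quasi-Clique Merging: (1) seed edges per [lmqcm_seeds()];
#' (2) greedy growth of each seed under the adaptive density criterion;
#' (3) candidates smaller than `min_module_size` are dropped; (4) clusters
#' with overlap `|A∩B| / min(|A|, |B|) >= beta` are merged (set union) to a
#' fixed point, largest first; (5) surviving modules are labelled by size
#' rank (1 = largest). Output is deterministic and invariant to gene-order
#' permutation of the input.
#'
#' `gamma` applies to the matrix actually passed in. On a spectrally
#' normalized matrix ([normalize_weights()]) the weights are rescaled by the
#' gene degrees, so pass `scale_gamma = TRUE` to reinterpret `gamma` as a
#' fraction of the maximum off-diagonal weight (the convention of the
#' reference lmQCM implementation for normalized input).
#'
#' @param W Symmetric weight matrix, zero diagonal, gene ids as rownames.
#' @param params [lmqcm_params()].
#' @param label_prefix Prefix for module labels (e.g. `"M"`, `"R"`).
#' @param platform Platform tag stored on each module.
#' @param scale_gamma If `TRUE`, the seed threshold is
#'   `gamma * max(off-diagonal W)`.
#' @return Object of class `gene_module_list`: list of `gene_module`s, each
#'   with `label`, `genes` (sorted), `platform`, `size`, `density`.
#'   Pre-merge candidates (gene sets and their densities) are stored in
#'   `attr(, "candidates")`.
#' @export
lmqcm_mine <- function(W, params = lmqcm_params(), label_prefix = "M",
                       platform = label_prefix, scale_gamma = FALSE) {
  stopifnot(inherits(params, "lmqcm_params"), is.matrix(W), nrow(W) == ncol(W))
  ids <- rownames(W)
  if (is.null(ids)) {
    ids <- sprintf("g%05d", seq_len(nrow(W)))
    dimnames(W) <- list(ids, ids)
  }
  ord <- order(ids)
  W <- W[ord, ord]
  ids <- ids[ord]
  diag(W) <- 0
  gamma <- params$gamma
  if (scale_gamma) gamma <- gamma * max(W)
  seeds <- lmqcm_seeds(W, gamma)
  if (nrow(seeds) == 0L) {
    message("no edge reaches the seed threshold; returning no modules")
    out <- structure(list(), class = "gene_module_list")
    attr(out, "candidates") <- list()
    return(out)
  }
  pos <- match(seeds$gene1, ids)
  pos2 <- match(seeds$gene2, ids)
  cand <- vector("list", nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    cand[[s]] <- sort(ids[grow_from_seed(W, pos[s], pos2[s], params$alpha, params$t)])
  }
  cand <- unique(cand)
  cand <- cand[vapply(cand, length, integer(1)) >= params$min_module_size]
  candidates <- lapply(cand, function(g) {
    list(genes = g, density = weighted_density(W, g))
  })

  # merge phase: repeat until no pair overlaps by >= beta of the smaller set
  sets <- cand
  if (length(sets) > 1) {
    repeat {
      o <- order(-vapply(sets, length, integer(1)),
                 vapply(sets, function(g) g[1], character(1)))
      sets <- sets[o]
      merged <- FALSE
      for (a in seq_len(length(sets) - 1)) {
        for (b in (a + 1):length(sets)) {
          ov <- length(intersect(sets[[a]], sets[[b]])) /
            min(length(sets[[a]]), length(sets[[b]]))
          if (ov >= params$beta) {
            sets[[a]] <- sort(union(sets[[a]], sets[[b]]))
            sets[[b]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  o <- order(-vapply(sets, length, integer(1)),
             vapply(sets, function(g) g[1], character(1)))
  sets <- sets[o]
  modules <- lapply(seq_along(sets), function(r) {
    structure(list(label = sprintf("%s%d", label_prefix, r),
                   genes = sets[[r]],
                   platform = platform,
                   size = length(sets[[r]]),
                   density = weighted_density(W, sets[[r]])),
              class = "gene_module")
  })
  out <- structure(modules, class = "gene_module_list")
  attr(out, "candidates") <- candidates
  out
}

#' @export
print.gene_module_list <- function(x, ...) {
  cat("lmQCM modules:", length(x), "\n")
  for (m in x) {
    cat(sprintf("  %-5s size %3d  density %.3f  [%s]\n",
                m$label, m$size, m$density, m$platform))
  }
  invisible(x)
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("gene module %s (%s): %d genes, density %.3f\n",
              x$label, x$platform, x$size, x$density))
  cat("  ", paste(utils::head(x$genes, 10), collapse = ", "),
      if (x$size > 10) "...", "\n")
  invisible(x)
}
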