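#' Scaled-exponential patient affinity kernel
#'
#' Builds the raw patient-similarity matrix from per-sample feature vectors
#' (e.g. eigengenes): `W(i, j) = exp(-d^2(i, j) / (mu * eps_ij))` where `d`
#' is the Euclidean distance and
#' `eps_ij = (mean_K(i) + mean_K(j) + d(i, j)) / 3`, with `mean_K(i)` the
#' mean distance of patient i to its K nearest neighbors. The diagonal is 1.
#'
#' @param features Numeric matrix, features x samples (sample ids as
#'   colnames).
#' @param K Neighbor count for the local scale (clamped to n - 1 with a
#'   warning).
#' @param mu Kernel scale hyperparameter (> 0).
#' @return Symmetric matrix with entries in `(0, 1]`, attribute
#'   `kind = "raw"`.
#' @export
affinity_kernel <- function(features, K = 30L, mu = 0.8) {
  stopifnot(is.matrix(features), mu > 0)
  ids <- colnames(features)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(ncol(features)))
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  n <- length(ids)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  if (K >= n) {
    warning("K >= number of samples; clamping K to n - 1 = ", n - 1)
    K <- n - 1L
  }
  D <- as.matrix(stats::dist(t(features)))
  mk <- vapply(seq_len(n), function(i) {
    mean(sort(D[i, -i])[seq_len(K)])
  }, numeric(1))
  eps <- (outer(mk, mk, "+") + D) / 3
  W <- exp(-D^2 / (mu * eps))
  diag(W) <- 1
  W <- (W + t(W)) / 2
  dimnames(W) <- list(ids, ids)
  attr(W, "kind") <- "raw"
  W
}

#' Full row normalization of an affinity matrix
#'
#' Off-diagonal entries are divided by twice their row's off-diagonal sum;
#' the diagonal is set to 1/2. Every row then sums to exactly 1. This is the
#' full-information state matrix of the similarity-network-fusion diffusion.
#'
#' @param W Raw nonnegative affinity matrix.
#' @return Normalized matrix, attribute `kind = "full_normalized"`.
#' @export
snf_full_normalize <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  off <- rowSums(W) - diag(W)
  if (any(off <= 0))
    stop("row(s) with zero off-diagonal sum cannot be normalized", call. = FALSE)
  P <- W / (2 * off)
  diag(P) <- 1 / 2
  dimnames(P) <- dimnames(W)
  attr(P, "kind") <- "full_normalized"
  P
}

#' Sparse K-nearest-neighbor diffusion kernel
#'
#' For each patient i, the K most similar other patients form the
#' neighborhood `N_i`; entries on `N_i` are the raw weights divided by twice
#' their sum over `N_i`, all other entries are zero. Each row sums to 1/2 on
#' its neighbor support. Ties at the K-th neighbor are broken by smallest
#' sample id.
#'
#' @param W Raw affinity matrix.
#' @param K Neighborhood size (1 <= K < n).
#' @return Sparse (mostly zero) matrix, attribute `kind = "knn_kernel"`.
#' @export
snf_knn_kernel <- function(W, K) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  n <- nrow(W)
  if (K < 1 || K >= n) stop("K must satisfy 1 <= K < n", call. = FALSE)
  ids <- rownames(W)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(-W[i, others], ids[others])][seq_len(K)]
    s <- sum(W[i, nb])
    if (s <= 0) stop("patient with zero similarity to all neighbors", call. = FALSE)
    S[i, nb] <- W[i, nb] / (2 * s)
  }
  attr(S, "kind") <- "knn_kernel"
  S
}

#' Similarity Network Fusion of two patient networks
#'
#' Cross-diffusion of two raw affinity matrices over the same patients:
#' each view's state matrix is initialized by full normalization
#' ([snf_full_normalize()]); each view's sparse KNN kernel
#' ([snf_knn_kernel()]) is computed once from the raw matrix; then for
#' `iters` rounds the states are updated as
#' `P1 <- S1 %*% P2 %*% t(S1)` and `P2 <- S2 %*% P1 %*% t(S2)`
#' (in parallel), each update followed by symmetrization and
#' re-normalization for numerical stability. The fused network is the
#' average of the two final states.
#'
#' @param W1,W2 Raw affinity matrices over identical sample ids.
#' @param K Neighborhood size for the diffusion kernel (clamped to n - 1).
#' @param iters Number of diffusion iterations.
#' @return Symmetric nonnegative fused matrix, attribute `kind = "fused"`.
#' @export
snf_fuse <- function(W1, W2, K = 30L, iters = 20L) {
  stopifnot(is.matrix(W1), is.matrix(W2))
  ids <- rownames(W1)
  if (is.null(ids) || is.null(rownames(W2)) || !setequal(ids, rownames(W2)))
    stop("the two affinity matrices must share identical sample ids", call. = FALSE)
  W2 <- W2[ids, ids]
  n <- nrow(W1)
  if (K >= n) {
    warning("K >= number of samples; clamping K to n - 1 = ", n - 1)
    K <- n - 1L
  }
  P1 <- snf_full_normalize(W1)
  P2 <- snf_full_normalize(W2)
  S1 <- snf_knn_kernel(W1, K)
  S2 <- snf_knn_kernel(W2, K)
  for (it in seq_len(iters)) {
    P1n <- S1 %*% P2 %*% t(S1)
    P2n <- S2 %*% P1 %*% t(S2)
    P1 <- snf_full_normalize((P1n + t(P1n)) / 2)
    P2 <- snf_full_normalize((P2n + t(P2n)) / 2)
  }
  Wf <- (P1 + P2) / 2
  Wf <- (Wf + t(Wf)) / 2   # row normalization is mildly asymmetric
  attr(Wf, "kind") <- "fused"
  Wf
}

#' Spectral clustering of a patient similarity network
#'
#' Normalized-Laplacian spectral embedding (top eigenvectors of
#' `D^{-1/2} W D^{-1/2}`, rows renormalized to unit length) followed by
#' k-means with a fixed seed and multiple restarts.
#'
#' @param W Symmetric nonnegative affinity matrix.
#' @param n_clusters Number of clusters (2 <= n_clusters <= n).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts (default 50).
#' @return Integer cluster labels in `0 .. n_clusters - 1`, named by sample.
#' @export
spectral_cluster <- function(W, n_clusters, seed = 1L, nstart = 50L) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  n <- nrow(W)
  if (n_clusters < 2 || n_clusters > n)
    stop("n_clusters must be in [2, n]", call. = FALSE)
  ids <- rownames(W)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  if (n_clusters == n)
    return(stats::setNames(seq_len(n) - 1L, ids))
  ncomp <- n_components(W > 0)
  if (ncomp > n_clusters)
    warning("graph has ", ncomp, " connected components but only ",
            n_clusters, " clusters requested")
  d <- rowSums(W)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  A <- W * outer(s, s)
  ev <- eigen(A, symmetric = TRUE)
  U <- ev$vectors[, seq_len(n_clusters), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn > 0, rn, 1)
  set.seed(seed)
  km <- stats::kmeans(U, centers = n_clusters, nstart = nstart, iter.max = 100)
  stats::setNames(as.integer(km$cluster) - 1L, ids)
}

# number of connected components of a logical adjacency matrix
n_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- 0L
  for (v in seq_len(n)) {
    if (seen[v]) next
    comps <- comps + 1L
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[u, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}
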