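toy_expr <- function(mat, genes = sprintf("g%02d", seq_len(nrow(mat)))) {
  dimnames(mat) <- list(genes, sprintf("s%02d", seq_len(ncol(mat))))
  mat
}

test_that("spearman weights match hand-computed rank correlations", {
  x <- toy_expr(rbind(c(1, 2, 3), c(10, 20, 30), c(3, 1, 2)))
  W <- spearman_weight_matrix(x)
  expect_equal(W["g01", "g02"], 1)            # same monotone order
  expect_equal(W["g01", "g03"], 0.5)          # 1 - 6*6/(3*8) = -0.5, |.| = 0.5
  expect_equal(diag(W), c(g01 = 0, g02 = 0, g03 = 0))
  expect_true(isSymmetric(unname(W)))
  expect_false(attr(W, "normalized"))
})

test_that("constant genes get zero weights with a warning", {
  x <- toy_expr(rbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(4, 3, 2, 1)))
  expect_warning(W <- spearman_weight_matrix(x), "constant")
  expect_equal(unname(W["g02", ]), c(0, 0, 0))
  expect_equal(W["g01", "g03"], 1)
})

test_that("independent long genes have uniformly small weights", {
  set.seed(42)
  x <- toy_expr(matrix(rnorm(4 * 200), 4, 200))
  W <- spearman_weight_matrix(x)
  expect_lt(max(W), 0.4)
})

test_that("spectral normalization divides by sqrt of degree products", {
  W <- matrix(0.6, 3, 3); diag(W) <- 0
  dimnames(W) <- list(letters[1:3], letters[1:3])
  Wn <- normalize_weights(W)
  # all degrees 1.2 -> each off-diagonal becomes 0.6/1.2 = 0.5
  expect_equal(unname(Wn[upper.tri(Wn)]), rep(0.5, 3))
  expect_true(attr(Wn, "normalized"))
})

test_that("normalization commutes with gene permutation and is bounded by 1", {
  set.seed(3)
  for (rep in 1:5) {
    W <- random_weight_matrix(8)
    Wn <- normalize_weights(W)
    expect_true(isSymmetric(unname(Wn)))
    expect_lte(max(Wn), 1 + 1e-12)
    perm <- sample(8)
    expect_equal(normalize_weights(W[perm, perm]), Wn[perm, perm],
                 ignore_attr = TRUE)
  }
})

test_that("isolated gene rows stay zero under normalization", {
  W <- matrix(c(0, 0.5, 0, 0.5, 0, 0, 0, 0, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(Wn <- normalize_weights(W), "isolated")
  expect_equal(unname(Wn[3, ]), c(0, 0, 0))
})

test_that("weighted density matches direct sums", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- W["b", "a"] <- 0.9
  W["a", "c"] <- W["c", "a"] <- 0.8
  W["b", "c"] <- W["c", "b"] <- 0.7
  expect_equal(weighted_density(W, letters[1:3]), 0.8)
  expect_equal(weighted_density(W, c("a", "b")), 0.9)
  U <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4])); diag(U) <- 0
  expect_equal(weighted_density(U, letters[1:4]), 1)
  expect_error(weighted_density(W, "a"), "fewer than 2")
})

test_that("seed edges are local-maximum edges above gamma, sorted by weight", {
  W <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["b", "a"] <- 0.9
  W["c", "d"] <- W["d", "c"] <- 0.85
  W["b", "c"] <- W["c", "b"] <- 0.82   # above gamma but not a local max
  diag(W) <- 0
  s <- lmqcm_seeds(W, 0.8)
  expect_equal(s$gene1, c("a", "c"))
  expect_equal(s$gene2, c("b", "d"))
  expect_equal(s$weight, c(0.9, 0.85))
})

test_that("raising gamma never increases the number of seed edges", {
  set.seed(10)
  for (rep in 1:10) {
    W <- random_weight_matrix(10)
    counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.95),
                     function(g) nrow(lmqcm_seeds(W, g)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("a planted triangle grows to exactly itself", {
  ids <- letters[1:6]
  W <- matrix(0.10, 6, 6, dimnames = list(ids, ids))
  W[1:3, 1:3] <- 0.95
  diag(W) <- 0
  mods <- lmqcm_mine(W, lmqcm_params(gamma = 0.8, min_module_size = 3))
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$genes, c("a", "b", "c"))
  expect_equal(mods[[1]]$density, 0.95)
})

test_that("disjoint cliques stay separate, overlapping cliques merge", {
  ids <- letters[1:10]
  W <- matrix(0.10, 10, 10, dimnames = list(ids, ids))
  W[1:4, 1:4] <- 0.95; W[5:8, 5:8] <- 0.95
  diag(W) <- 0
  mods <- lmqcm_mine(W, lmqcm_params(gamma = 0.8, min_module_size = 3))
  expect_length(mods, 2)
  expect_setequal(mods[[1]]$genes, letters[1:4])
  expect_setequal(mods[[2]]$genes, letters[5:8])

  ids <- letters[1:6]
  W <- matrix(0.10, 6, 6, dimnames = list(ids, ids))
  W[1:4, 1:4] <- 0.95; W[3:6, 3:6] <- 0.95   # share c, d: overlap 2/4 >= 0.4
  diag(W) <- 0
  mods <- lmqcm_mine(W, lmqcm_params(gamma = 0.8, min_module_size = 3))
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$genes, ids)
})

test_that("no edge above gamma yields an empty module list", {
  W <- random_weight_matrix(5) * 0.3
  expect_message(mods <- lmqcm_mine(W, lmqcm_params(gamma = 0.9)), "no edge")
  expect_length(mods, 0)
})

test_that("mining is invariant to gene-order permutation", {
  set.seed(8)
  co <- small_cohort(seed = 31, n = 80, p = 100,
                     shared = list(S1 = list(size = 15, cor = 0.85)),
                     u1 = list(), u2 = list(), beta = NULL)
  W <- spearman_weight_matrix(co$expr1)
  p <- lmqcm_params(min_module_size = 5)
  ref <- lmqcm_mine(W, p)
  perm <- sample(nrow(W))
  alt <- lmqcm_mine(W[perm, perm], p)
  expect_equal(lapply(ref, `[[`, "genes"), lapply(alt, `[[`, "genes"))
})

test_that("miner agrees with the brute-force oracle on small random graphs", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    W <- random_weight_matrix(n)
    got <- lmqcm_mine(W, lmqcm_params(gamma = 0.5, min_module_size = 2))
    want <- oracle_lmqcm(W, gamma = 0.5, alpha = 1, t = 1, beta = 0.4,
                         min_size = 2)
    expect_equal(lapply(got, `[[`, "genes"), want)
  }
})

test_that("scale_gamma reinterprets the threshold on normalized input", {
  ids <- letters[1:6]
  W <- matrix(0.10, 6, 6, dimnames = list(ids, ids))
  W[1:3, 1:3] <- 0.95
  diag(W) <- 0
  Wn <- normalize_weights(W)
  # no normalized weight reaches 0.8, so the unscaled threshold finds nothing
  expect_message(m0 <- lmqcm_mine(Wn, lmqcm_params(gamma = 0.8, min_module_size = 3)),
                 "no edge")
  expect_length(m0, 0)
  m1 <- lmqcm_mine(Wn, lmqcm_params(gamma = 0.8, min_module_size = 3),
                   scale_gamma = TRUE)
  expect_length(m1, 1)
  expect_setequal(m1[[1]]$genes, c("a", "b", "c"))
})
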