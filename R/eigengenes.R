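#' Z-score genes across samples
#'
#' Each gene row is centred and scaled to unit sample (n-1) standard
#' deviation. Zero-variance genes become all-zero rows, with a warning.
#'
#' @param expr Numeric matrix, genes x samples.
#' @return Matrix of the same shape.
#' @export
zscore_genes <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2) stop("need at least 2 samples to z-score", call. = FALSE)
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning("zero-variance gene(s) set to all-zero rows: ",
            paste(utils::head(rownames(expr)[zero], 5), collapse = ", "))
    sdv[zero] <- 1
  }
  out <- (expr - mu) / sdv
  out[zero, ] <- 0
  out
}

#' Summarize a gene module into an eigengene
#'
#' The eigengene is the first principal-component score vector over samples
#' of the z-scored module submatrix (computed by singular value
#' decomposition), rescaled to unit sample variance. The sign is fixed so
#' that the eigengene correlates non-negatively with the per-sample mean of
#' the z-scored module genes.
#'
#' @param expr Numeric matrix, genes x samples, gene ids as rownames.
#' @param module A `gene_module` or character vector of gene ids.
#' @return Numeric vector, one value per sample (named by sample id).
#' @export
summarize_module <- function(expr, module) {
  genes <- if (is.list(module)) module$genes else module
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("module gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  Z <- zscore_genes(expr[genes, , drop = FALSE])
  if (all(Z == 0)) {
    warning("degenerate module (all genes constant): zero eigengene")
    return(stats::setNames(numeric(ncol(expr)), colnames(expr)))
  }
  sv <- svd(Z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  m <- colMeans(Z)
  if (stats::sd(m) > 0 && stats::cor(e, m) < 0) e <- -e
  e <- e / stats::sd(e)
  stats::setNames(e, colnames(expr))
}

#' Eigengene matrix for a list of modules
#'
#' @param expr Numeric matrix, genes x samples.
#' @param modules `gene_module_list` or list of gene-id vectors.
#' @return Matrix, modules x samples; rows are unit-variance eigengenes in
#'   the order of `modules`, rownames are module labels, `platform`
#'   attribute copied from `expr`.
#' @export
eigengene_matrix <- function(expr, modules) {
  if (length(modules) == 0L) stop("no modules to summarize", call. = FALSE)
  rows <- lapply(modules, function(m) summarize_module(expr, m))
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    if (is.list(m) && !is.null(m$label)) m$label else sprintf("E%d", i)
  }, character(1))
  colnames(out) <- colnames(expr)
  attr(out, "platform") <- attr(expr, "platform")
  out
}
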