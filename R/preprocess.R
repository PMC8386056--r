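#' Center each gene's expression profile
#'
#' Subtracts the per-gene mean so every row has mean zero. Pearson
#' correlation is location invariant, but PCA and metric learning are not,
#' so centering is applied before either. Rows with zero variance become
#' all-zero rows; a warning reports how many.
#'
#' @param x expression matrix.
#' @return expression matrix of identical shape, rows centered.
#' @export
standardize <- function(x) {
  v <- unclass(x)
  ctr <- v - rowMeans(v)
  flat <- apply(v, 1L, function(r) max(r) == min(r))
  if (any(flat))
    warning(sprintf("%d gene(s) with zero variance set to all-zero rows", sum(flat)),
            call. = FALSE)
  expression_matrix(ctr)
}

# Flip each component so its largest-|loading| entry is positive; SVD signs
# are backend-dependent, this pins them.
fix_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Project genes onto their top-k principal components
#'
#' Rows (genes) are the observations and samples are the features; columns
#' are mean-centered and the top-k right singular directions give the score
#' matrix. A fixed sign convention (largest-magnitude loading positive) makes
#' the output deterministic across linear-algebra backends; `seed` is part of
#' the interface for reproducibility bookkeeping but the computation itself
#' is deterministic.
#'
#' @param x expression matrix or plain numeric matrix (genes x samples).
#' @param k number of components, `k <= min(n, d)`.
#' @param seed unused except to document determinism; kept for interface
#'   stability.
#' @return n x k numeric matrix of PC scores, rownames preserved, with the
#'   per-component explained variance fractions in attribute
#'   `"explained_variance"`.
#' @export
pca_project <- function(x, k, seed = 1L) {
  v <- unclass(x)
  if (k < 1L || k > min(dim(v)))
    stop(sprintf("k must be in [1, %d]", min(dim(v))), call. = FALSE)
  vc <- sweep(v, 2L, colMeans(v))
  sv <- svd(vc, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  fx <- fix_signs(scores, sv$v)
  scores <- fx$scores
  rownames(scores) <- rownames(v)
  colnames(scores) <- paste0("PC", seq_len(k))
  tot <- sum(sv$d^2)
  attr(scores, "explained_variance") <-
    if (tot > 0) sv$d[seq_len(k)]^2 / tot else rep(0, k)
  scores
}

#' Project source and target cohorts to a common feature dimension
#'
#' The two cohorts generally have different patient counts, but the fusion
#' objective needs per-gene feature vectors of equal length; each matrix is
#' therefore independently PCA-projected to `k` features. The default k = 80
#' reflects the stable accuracy plateau observed for feature counts in
#' [70, 100].
#'
#' @param source,target expression matrices sharing the same gene order.
#' @param k common feature count; `k <= min(d_source, d_target, n)`.
#' @param seed passed through to [pca_project()].
#' @return list(source, target) of n x k score matrices.
#' @export
harmonize_dims <- function(source, target, k = 80L, seed = 1L) {
  if (!identical(rownames(source), rownames(target)))
    stop("source and target gene order must be identical (run align_gene_universe)",
         call. = FALSE)
  if (k > min(ncol(source), ncol(target), nrow(source)))
    stop("k exceeds min(d_source, d_target, n)", call. = FALSE)
  list(source = pca_project(source, k, seed),
       target = pca_project(target, k, seed))
}
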