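#' Cross-domain gene affinity matrix
#'
#' Entry s_ij is the absolute Pearson correlation between target gene i's
#' feature vector and source gene j's feature vector: rows index TARGET
#' genes, columns index SOURCE genes, matching how the fusion objective
#' consumes s_ij together with the target projection. The matrix is NOT
#' symmetrized — it is a bipartite target-by-source similarity even though
#' both sides index the same gene universe — so row sums and column sums are
#' kept as two separate degree diagonals.
#'
#' @param target_feats,source_feats n x k matrices with the same gene order
#'   and k >= 3 features (Pearson needs >= 3 paired coordinates).
#' @return list with `values` (n x n, entries in [0, 1]), `row_degree` and
#'   `col_degree` vectors; class `"affinity_matrix"`.
#' @export
build_affinity <- function(target_feats, source_feats) {
  if (!identical(dim(target_feats), dim(source_feats)))
    stop("feature matrices must have identical shape", call. = FALSE)
  if (!identical(rownames(target_feats), rownames(source_feats)))
    stop("feature matrices must share gene order", call. = FALSE)
  if (ncol(target_feats) < 3L)
    stop("need at least 3 features for Pearson correlation", call. = FALSE)
  s <- suppressWarnings(abs(stats::cor(t(target_feats), t(source_feats))))
  if (anyNA(s)) {
    warning(sprintf("%d zero-variance feature vector pair(s); affinity set to 0",
                    sum(is.na(s))), call. = FALSE)
    s[is.na(s)] <- 0
  }
  s <- pmin(s, 1)  # guard FP overshoot of |cor|
  dimnames(s) <- list(rownames(target_feats), rownames(source_feats))
  new_affinity(s)
}

new_affinity <- function(s) {
  structure(list(values = s, row_degree = rowSums(s), col_degree = colSums(s)),
            class = "affinity_matrix")
}

#' Keep only the strongest affinities per target gene
#'
#' The dense n x n affinity is quadratic in the gene count; for large
#' universes only the `top_m` largest entries per row are kept, the rest
#' zeroed, and degrees recomputed. Ties at the cutoff are broken by column
#' index order (keep lower index) for determinism.
#'
#' @param s affinity matrix.
#' @param top_m entries kept per row, `top_m <= n` (columns).
#' @return sparsified affinity matrix.
#' @export
sparsify_affinity <- function(s, top_m) {
  v <- s$values
  if (top_m > ncol(v)) stop("top_m exceeds number of source genes", call. = FALSE)
  if (top_m < ncol(v)) {
    for (i in seq_len(nrow(v))) {
      keep <- order(-v[i, ], seq_len(ncol(v)), method = "radix")[seq_len(top_m)]
      drop <- setdiff(seq_len(ncol(v)), keep)
      v[i, drop] <- 0
    }
  }
  new_affinity(v)
}
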