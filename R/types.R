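#' Construct an expression matrix
#'
#' An expression matrix holds one cohort's gene expression profiles as a
#' numeric genes x samples matrix (e.g. log-FPKM). Rows are genes, columns
#' are samples; both carry unique identifiers. At least 2 genes and 3
#' samples are required, because Pearson correlation over samples is
#' degenerate below 3 points.
#'
#' @param values numeric matrix with unique rownames (gene ids) and unique
#'   colnames (sample ids); no missing values.
#' @return the validated matrix with class `"expression_matrix"`.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated gene identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample identifier(s)", call. = FALSE)
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]),
         call. = FALSE)
  }
  if (nrow(values) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (ncol(values) < 3L) stop("need at least 3 samples", call. = FALSE)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Gene identifiers of an object
#' @param x an expression matrix, weighted network or affinity matrix.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(x) {
  if (inherits(x, "affinity_matrix")) return(rownames(x$values))
  rownames(x)
}

#' Construct a binary pathogenic-gene label vector
#'
#' Labels are aligned to a gene universe: 1 marks a known pathogenic gene,
#' 0 everything else. Both classes must be present (metric learning needs
#' positives and negatives).
#'
#' @param labels integer/numeric vector of 0/1, named by gene id, or a
#'   character vector of pathogenic gene ids together with `gene_ids`.
#' @param gene_ids gene universe when `labels` is a character vector of
#'   positive ids.
#' @return named integer 0/1 vector with class `"pathogenic_labels"`.
#' @export
pathogenic_labels <- function(labels, gene_ids = NULL) {
  if (is.character(labels)) {
    if (is.null(gene_ids))
      stop("gene_ids required when labels given as id list", call. = FALSE)
    labels <- as.integer(gene_ids %in% labels)
    names(labels) <- gene_ids
  }
  if (is.null(names(labels)))
    stop("labels must be named by gene id", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  ids <- if (is.character(gene_ids) && length(gene_ids) == length(labels))
    gene_ids else names(labels)
  labels <- as.integer(labels)
  names(labels) <- ids
  if (sum(labels) == 0L || sum(labels) == length(labels))
    stop("labels must contain both classes (>=1 pathogenic and >=1 background gene)",
         call. = FALSE)
  structure(labels, class = "pathogenic_labels")
}

#' Construct an undirected weighted gene network
#'
#' Adjacency is a symmetric nonnegative matrix over the gene universe.
#' Self-loops are disallowed: the diagonal is forced to zero, because the
#' closed-form weight update gives w_ii = 1 trivially (zero distance) and a
#' unit self-loop would distort degree-based propagation.
#'
#' @param weights symmetric nonnegative numeric matrix with gene ids as
#'   dimnames.
#' @param tol symmetry tolerance.
#' @return matrix with class `"weighted_network"`, zero diagonal.
#' @export
weighted_network <- function(weights, tol = 1e-10) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("weights must be a numeric matrix", call. = FALSE)
  if (nrow(weights) != ncol(weights))
    stop("weights must be square", call. = FALSE)
  if (is.null(rownames(weights)))
    stop("weights need gene ids as dimnames", call. = FALSE)
  if (any(weights < 0))
    stop("weights must be nonnegative", call. = FALSE)
  if (max(abs(weights - t(weights))) > tol)
    stop("weights must be symmetric (undirected network)", call. = FALSE)
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  colnames(weights) <- rownames(weights)
  class(weights) <- c("weighted_network", class(weights))
  weights
}

#' Node degrees of a weighted network
#' @param w weighted network.
#' @return numeric vector d_i = sum_j w_ij.
#' @export
network_degree <- function(w) rowSums(unclass(w))

#' Graph Laplacian L = D - W
#' @param w weighted network.
#' @return numeric matrix; rows sum to zero, positive semidefinite for
#'   nonnegative symmetric W.
#' @export
network_laplacian <- function(w) {
  w <- unclass(w)
  diag(rowSums(w)) - w
}

#' Construct a gene ranking
#'
#' A ranking is a total order over genes by a strictly positive relevance
#' score. Ties are broken deterministically by gene id (C-locale
#' lexicographic order) so results are reproducible across platforms.
#'
#' @param gene_id character vector.
#' @param score strictly positive numeric vector.
#' @return data.frame (rank, gene_id, score) with class `"gene_ranking"`,
#'   sorted by decreasing score.
#' @export
gene_ranking <- function(gene_id, score) {
  if (length(gene_id) != length(score))
    stop("gene_id and score lengths differ", call. = FALSE)
  if (length(score) && any(!is.finite(score) | score <= 0))
    stop("ranking scores must be finite and strictly positive", call. = FALSE)
  o <- order(-score, gene_id, method = "radix")
  out <- data.frame(rank = seq_along(o),
                    gene_id = as.character(gene_id[o]),
                    score = as.numeric(score[o]),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Top-k gene ids of a ranking
#' @param r gene ranking.
#' @param k number of genes.
#' @return character vector of length `min(k, nrow(r))`.
#' @export
top_genes <- function(r, k) r$gene_id[seq_len(min(k, nrow(r)))]
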