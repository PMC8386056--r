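#' Read an expression matrix from TSV
#'
#' Expected layout: tab-separated, header row of sample ids, first column of
#' gene ids. Duplicate gene ids and non-numeric cells are hard errors naming
#' the offending row/column; this catches silent `NA` coercion early.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("expression TSV needs gene column + samples", call. = FALSE)
  genes <- raw[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicated gene identifier(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  samples <- colnames(raw)[-1L]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(length(genes))))
  if (length(genes) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], samples[bad[1L, 2L]]), call. = FALSE)
  }
  dimnames(vals) <- list(genes, samples)
  expression_matrix(vals)
}

#' Write an expression matrix to TSV
#' @param x expression matrix.
#' @param path file path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one id per line, '#' comments allowed)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Read an undirected weighted network from a 3-column edge list TSV
#'
#' Columns: gene_a, gene_b, weight; one line per unordered pair. When
#' `universe` is supplied the adjacency is built over that gene ordering and
#' edges outside it are dropped; otherwise the universe is the sorted set of
#' ids seen in the file.
#'
#' @param path file path.
#' @param universe optional character vector fixing gene order.
#' @return a [weighted_network()].
#' @export
read_network <- function(path, universe = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("edge list needs 3 columns", call. = FALSE)
  a <- as.character(df[[1L]]); b <- as.character(df[[2L]])
  wt <- as.numeric(df[[3L]])
  if (is.null(universe)) universe <- sort(unique(c(a, b)), method = "radix")
  keep <- a %in% universe & b %in% universe
  a <- a[keep]; b <- b[keep]; wt <- wt[keep]
  n <- length(universe)
  m <- matrix(0, n, n, dimnames = list(universe, universe))
  ia <- match(a, universe); ib <- match(b, universe)
  m[cbind(ia, ib)] <- wt
  m[cbind(ib, ia)] <- wt
  weighted_network(m)
}

#' Write a weighted network as an edge list TSV
#'
#' Emits one line per unordered pair with positive weight.
#' @param w weighted network.
#' @param path file path.
#' @export
write_network <- function(w, path) {
  m <- unclass(w)
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  df <- data.frame(gene_a = rownames(m)[idx[, 1L]],
                   gene_b = colnames(m)[idx[, 2L]],
                   weight = m[idx], stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b, method = "radix"), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene ranking to TSV (rank, gene_id, score)
#' @param r gene ranking.
#' @param path file path.
#' @export
write_ranking <- function(r, path) {
  utils::write.table(as.data.frame(unclass(r)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene ranking written by [write_ranking()]
#' @param path file path.
#' @return a [gene_ranking()].
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gene_ranking(as.character(df$gene_id), as.numeric(df$score))
}

#' Restrict source and target cohorts to their shared gene universe
#'
#' Both matrices are subset to the intersection of gene ids, in the order of
#' the source matrix, and labels are subset accordingly. Counts of dropped
#' genes are reported via [message()]. Cross-cohort analyses assume both
#' domains index the same genes, so an empty intersection is a hard error.
#'
#' @param source,target expression matrices.
#' @param labels pathogenic labels aligned to the source genes.
#' @return list(source, target, labels) over the common universe.
#' @export
align_gene_universe <- function(source, target, labels) {
  common <- intersect(rownames(source), rownames(target))
  if (!length(common))
    stop("source and target share no gene identifiers", call. = FALSE)
  ds <- nrow(source) - length(common)
  dt <- nrow(target) - length(common)
  if (ds || dt)
    message(sprintf("align_gene_universe: dropped %d source and %d target genes",
                    ds, dt))
  lab <- unclass(labels)[common]
  names(lab) <- common
  list(source = expression_matrix(unclass(source)[common, , drop = FALSE]),
       target = expression_matrix(unclass(target)[common, , drop = FALSE]),
       labels = pathogenic_labels(lab))
}
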