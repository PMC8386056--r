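upper_pairs <- function(m) which(upper.tri(m), arr.ind = TRUE)

#' Fraction of strong network edges confirmed by a reference interactome
#'
#' Edges of the weighted network whose weight exceeds
#' `alpha_mult x mean(positive off-diagonal weights)` are selected and the
#' fraction of them present in the reference network (treated as unweighted
#' presence/absence over unordered pairs) is returned. The denominator is
#' the number of selected edges. The two networks are intersected on their
#' shared gene universe, with a warning when genes are dropped.
#'
#' @param net weighted network under evaluation.
#' @param reference weighted network of validated interactions.
#' @param alpha_mult threshold multiplier (>= 0); the customary sweep runs
#'   from 1.2 to 2.0 in steps of 0.02 (see [overlap_sweep()]).
#' @return fraction in [0, 1]; 0 with a warning when no edge passes the
#'   threshold.
#' @export
edge_overlap_fraction <- function(net, reference, alpha_mult) {
  if (alpha_mult < 0) stop("alpha_mult must be >= 0", call. = FALSE)
  nm <- as_matrix_w(net); rm_ <- as_matrix_w(reference)
  common <- intersect(rownames(nm), rownames(rm_))
  if (!length(common)) stop("no shared genes with reference", call. = FALSE)
  if (length(common) < nrow(nm) || length(common) < nrow(rm_))
    warning("networks intersected on shared gene universe", call. = FALSE)
  nm <- nm[common, common]; rm_ <- rm_[common, common]
  ut <- upper.tri(nm)
  wts <- nm[ut]
  pos <- wts[wts > 0]
  if (!length(pos)) {
    warning("network has no positive edges", call. = FALSE)
    return(0)
  }
  thr <- alpha_mult * mean(pos)
  sel <- ut & nm > thr
  n_sel <- sum(sel)
  if (n_sel == 0L) {
    warning("no edge passes the threshold", call. = FALSE)
    return(0)
  }
  sum(rm_[sel] > 0) / n_sel
}

#' Overlap fractions across a threshold sweep
#'
#' @param net,reference as in [edge_overlap_fraction()].
#' @param alpha_mults vector of multipliers; default seq(1.2, 2.0, by 0.02).
#' @return data.frame(alpha_mult, overlap).
#' @export
overlap_sweep <- function(net, reference, alpha_mults = seq(1.2, 2.0, by = 0.02)) {
  data.frame(alpha_mult = alpha_mults,
             overlap = vapply(alpha_mults, function(am)
               suppressWarnings(edge_overlap_fraction(net, reference, am)),
               numeric(1L)))
}

#' Fraction of the top-k ranked genes that are pathogenic
#'
#' @param r gene ranking.
#' @param truth [pathogenic_labels()] over (a superset of) the ranked genes.
#' @param k cutoff, `k <=` number of ranked genes.
#' @return |top-k intersect positives| / k.
#' @export
topk_accuracy <- function(r, truth, k) {
  if (k < 1L || k > nrow(r)) stop("k out of range", call. = FALSE)
  pos <- names(unclass(truth))[unclass(truth) == 1L]
  sum(top_genes(r, k) %in% pos) / k
}

#' Pathogenic genes found by only one of two rankings
#'
#' Counts truth-positive genes in the top-k of one ranking but not the
#' other, in both directions.
#'
#' @param r_a,r_b gene rankings over the same universe.
#' @param truth [pathogenic_labels()].
#' @param k cutoff.
#' @return named integer vector c(a_only, b_only).
#' @export
uniquely_ranked <- function(r_a, r_b, truth, k) {
  pos <- names(unclass(truth))[unclass(truth) == 1L]
  ta <- intersect(top_genes(r_a, k), pos)
  tb <- intersect(top_genes(r_b, k), pos)
  c(a_only = length(setdiff(ta, tb)), b_only = length(setdiff(tb, ta)))
}

#' Gene co-expression network of one cohort
#'
#' The baseline network: edge weight is the absolute Pearson correlation of
#' the two genes' expression profiles within the cohort; diagonal zero.
#' Zero-variance genes get zero rows/columns with a warning.
#'
#' @param target expression matrix (or plain genes x samples matrix, d >= 3).
#' @return a [weighted_network()].
#' @export
coexpression_network <- function(target) {
  v <- unclass(target)
  if (ncol(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  w <- suppressWarnings(abs(stats::cor(t(v))))
  if (anyNA(w)) {
    warning("zero-variance gene(s): correlations set to 0", call. = FALSE)
    w[is.na(w)] <- 0
  }
  w <- pmin(w, 1)
  dimnames(w) <- list(rownames(v), rownames(v))
  diag(w) <- 0
  weighted_network(w)
}
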