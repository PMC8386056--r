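#' End-to-end transfer-learning gene prioritization
#'
#' Runs the full pipeline: align the gene universes, center the profiles,
#' build the cross-domain affinity matrix, learn the label-separating source
#' representation, fit the fused target network by alternating minimization,
#' and rank target genes by network propagation seeded with the source
#' pathogenic labels.
#'
#' When both cohorts have the same number of samples the affinity is
#' computed on the centered raw sample space (Pearson correlation needs
#' paired coordinates); when the sample counts differ it is computed in the
#' common PCA space. The PCA features always feed the metric-learning and
#' fusion stages.
#'
#' @param source expression matrix of the labeled cohort.
#' @param target expression matrix of the unlabeled cohort.
#' @param labels [pathogenic_labels()] for the source genes.
#' @param n_features common PCA dimension (default 80, capped at
#'   min(d_source, d_target, n)).
#' @param lambda fusion penalty weight (default 1).
#' @param r embedding dimension for the source representation; default =
#'   feature count.
#' @param n_neighbors,margin_weight,fidelity_weight,lmnn_max_iter
#'   metric-learning controls, see [fit_lmnn()].
#' @param max_iter,tol,step_init fusion optimizer controls, see
#'   [fit_fusion()].
#' @param method propagation algorithm for the final ranking.
#' @param alpha restart parameter of the propagation (PRINCE) or damping
#'   (PageRank).
#' @param seed seed recorded for reproducibility; the pipeline is
#'   deterministic given its inputs.
#' @return list with `ranking` (a [gene_ranking()]), `fusion`
#'   (a `"fusion_model"`), `representation`, `affinity`, `features`
#'   (the harmonized PCA scores) and `prior`; class `"fusionrank_fit"`.
#' @export
fuse_and_rank <- function(source, target, labels, n_features = 80L,
                          lambda = 1, r = NULL, n_neighbors = 3L,
                          margin_weight = 0.5, fidelity_weight = 5,
                          lmnn_max_iter = 100L,
                          max_iter = 200L, tol = 1e-5, step_init = 1e-2,
                          method = c("prince", "pagerank"), alpha = NULL,
                          seed = 1L) {
  method <- match.arg(method)
  al <- align_gene_universe(source, target, labels)
  src <- standardize(al$source)
  tgt <- standardize(al$target)
  k <- min(n_features, ncol(src), ncol(tgt), nrow(src))
  feats <- harmonize_dims(src, tgt, k = k, seed = seed)

  s <- if (ncol(src) == ncol(tgt)) {
    build_affinity(unclass(tgt), unclass(src))
  } else {
    build_affinity(feats$target, feats$source)
  }

  if (is.null(r)) r <- k
  rep_ <- fit_lmnn(feats$source, al$labels, r = r, n_neighbors = n_neighbors,
                   margin_weight = margin_weight,
                   fidelity_weight = fidelity_weight,
                   max_iter = lmnn_max_iter, seed = seed)
  fm <- fit_fusion(feats$target, s, rep_$A, lam = lambda, max_iter = max_iter,
                   tol = tol, step_init = step_init, seed = seed)
  prior <- build_prior_from_source(al$labels)
  if (is.null(alpha)) alpha <- if (method == "prince") 0.9 else 0.85
  ranking <- if (method == "prince") {
    prince_rank(fm$W, prior, alpha = alpha)
  } else {
    pagerank_rank(fm$W, damping = alpha, personalization = prior)
  }
  structure(list(ranking = ranking, fusion = fm, representation = rep_,
                 affinity = s, features = feats, prior = prior,
                 labels = al$labels, method = method, seed = seed),
            class = "fusionrank_fit")
}
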