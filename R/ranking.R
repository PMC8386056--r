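#' Symmetric degree normalization of a network
#'
#' Returns \eqn{\hat W = D^{-1/2} W D^{-1/2}}; isolated nodes (zero degree)
#' keep zero rows/columns. For nonnegative symmetric W the eigenvalues of
#' the normalized matrix lie in [-1, 1], which is what makes the propagation
#' iteration below a contraction for alpha < 1.
#'
#' @param w weighted network.
#' @return plain n x n numeric matrix.
#' @export
normalize_network <- function(w) {
  m <- as_matrix_w(w)
  d <- rowSums(m)
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  out <- m * tcrossprod(inv)
  dimnames(out) <- dimnames(m)
  out
}

#' Propagation prior from the source pathogenic labels
#'
#' The target cohort has no labels of its own; since both cohorts share the
#' gene universe, the only available seed vector for propagation is the
#' source label vector, L1-normalized.
#'
#' @param labels [pathogenic_labels()].
#' @return nonnegative vector summing to 1, named by gene id.
#' @export
build_prior_from_source <- function(labels) {
  y <- as.numeric(unclass(labels))
  names(y) <- names(unclass(labels))
  if (sum(y) == 0) stop("no pathogenic source genes: prior undefined", call. = FALSE)
  y / sum(y)
}

#' PRINCE-style network propagation ranking
#'
#' Iterates \eqn{F \leftarrow \alpha \hat W F + (1-\alpha) Y} on the
#' symmetrically normalized network to its unique fixed point
#' \eqn{(1-\alpha)(I - \alpha\hat W)^{-1} Y} (unique because the spectral
#' radius of \eqn{\alpha\hat W} is below 1). Scores are shifted by a tiny
#' epsilon so the returned ranking is strictly positive even for genes in
#' components that receive no prior mass.
#'
#' @param w weighted network.
#' @param prior nonnegative vector, length n or named by gene id, with at
#'   least one positive entry; L1-normalized internally.
#' @param alpha restart trade-off in (0,1); default 0.9, the customary
#'   value for this propagation scheme.
#' @param tol max-norm convergence threshold (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return a [gene_ranking()].
#' @export
prince_rank <- function(w, prior, alpha = 0.9, tol = 1e-10, max_iter = 10000L) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  m <- as_matrix_w(w)
  ids <- rownames(m)
  y <- align_prior(prior, ids)
  if (all(y == 0)) stop("prior must have a positive entry", call. = FALSE)
  y <- y / sum(y)
  wn <- normalize_network(w)
  f <- y
  for (i in seq_len(max_iter)) {
    f_new <- alpha * (wn %*% f)[, 1L] + (1 - alpha) * y
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  gene_ranking(ids, f + 1e-12)
}

align_prior <- function(prior, ids) {
  if (!is.null(names(prior))) {
    y <- rep(0, length(ids))
    names(y) <- ids
    common <- intersect(names(prior), ids)
    y[common] <- prior[common]
  } else {
    if (length(prior) != length(ids))
      stop("prior length must match network size", call. = FALSE)
    y <- as.numeric(prior)
  }
  if (any(y < 0)) stop("prior must be nonnegative", call. = FALSE)
  y
}

#' Personalized PageRank ranking
#'
#' Power iteration on the column-stochastic transition matrix of the
#' network with damping and a uniform (or supplied) teleport vector.
#' Dangling nodes (zero degree) redistribute their mass over the teleport
#' vector, so scores always sum to 1.
#'
#' @param w weighted network.
#' @param damping damping factor in (0,1); default 0.85.
#' @param personalization optional nonnegative teleport vector (length n or
#'   named); uniform when NULL.
#' @param tol L1 convergence threshold (default 1e-12).
#' @param max_iter iteration cap (default 10000).
#' @return a [gene_ranking()] whose scores sum to 1.
#' @export
pagerank_rank <- function(w, damping = 0.85, personalization = NULL,
                          tol = 1e-12, max_iter = 10000L) {
  if (!(damping > 0 && damping < 1)) stop("damping must be in (0,1)", call. = FALSE)
  m <- as_matrix_w(w)
  n <- nrow(m)
  ids <- rownames(m)
  tele <- if (is.null(personalization)) rep(1 / n, n) else {
    t0 <- align_prior(personalization, ids)
    if (sum(t0) == 0) stop("personalization must have a positive entry", call. = FALSE)
    t0 / sum(t0)
  }
  deg <- colSums(m)
  dangling <- deg == 0
  # column-stochastic transition: P[, j] = w[, j] / deg_j
  p <- m
  p[, !dangling] <- sweep(m[, !dangling, drop = FALSE], 2L, deg[!dangling], "/")
  p[, dangling] <- 0
  v <- tele
  for (i in seq_len(max_iter)) {
    v_new <- damping * ((p %*% v)[, 1L] + sum(v[dangling]) * tele) +
      (1 - damping) * tele
    if (sum(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new
  }
  gene_ranking(ids, pmax(v, 1e-300))
}
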