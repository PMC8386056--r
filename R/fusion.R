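as_matrix_w <- function(w) {
  if (inherits(w, "weighted_network")) unclass(w) else w
}
as_matrix_s <- function(s) {
  if (inherits(s, "affinity_matrix")) s$values else s
}

#' Fusion objective, elementwise (canonical) form
#'
#' The value being minimized when learning the fused network:
#' \deqn{\frac12 \sum_{i,j} \big[ s_{ij}\|x_i U - a_j\|^2
#'   + w_{ij}\|(x_i - x_j)U\|^2 + \lambda(\sqrt{w_{ij}} - 1)^2 \big]}
#' where x_i are target feature rows, a_j are rows of the learned source
#' representation, and the penalty drives weights towards 1 for strongly
#' coupled pairs. The sum runs over all ordered pairs including the
#' diagonal; the zero-diagonal convention of the network therefore adds a
#' constant lambda per gene, irrelevant to the minimizer. This elementwise
#' form is the canonical definition; the trace form must agree with it.
#'
#' @param u k x r projection of target features.
#' @param w weighted network (or plain matrix) of fused weights in [0, 1].
#' @param s affinity matrix (or plain matrix), rows = target genes.
#' @param target_feats n x k target feature matrix.
#' @param a n x r source representation.
#' @param lam positive penalty weight.
#' @return scalar objective value.
#' @export
objective_elementwise <- function(u, w, s, target_feats, a, lam) {
  if (lam <= 0) stop("lambda must be positive", call. = FALSE)
  wm <- as_matrix_w(w); sm <- as_matrix_s(s)
  p <- target_feats %*% u
  term_s <- sum(sm * cross_sqdist(p, a))
  term_w <- sum(wm * row_sqdist(p))
  term_pen <- lam * sum((sqrt(wm) - 1)^2)
  0.5 * (term_s + term_w + term_pen)
}

#' Fusion objective, matrix trace form
#'
#' Computes the same value as [objective_elementwise()] via matrix traces:
#' the pairwise target term through the graph Laplacian identity
#' \eqn{\sum_{ij} w_{ij}\|(x_i - x_j)U\|^2 = 2\,tr(U'X'L_W X U)} (note the
#' factor 2), and the affinity term through the separate row- and
#' column-degree diagonals of the asymmetric S:
#' \eqn{tr(U'X'D_r X U) - 2\,tr(U'X'SA) + tr(A'D_c A)}. The constants are
#' fixed by agreement with the elementwise oracle rather than by any printed
#' convention.
#'
#' @inheritParams objective_elementwise
#' @return scalar objective value, equal to the elementwise form to 1e-8
#'   relative.
#' @export
objective_traceform <- function(u, w, s, target_feats, a, lam) {
  if (lam <= 0) stop("lambda must be positive", call. = FALSE)
  wm <- as_matrix_w(w); sm <- as_matrix_s(s)
  x <- target_feats
  p <- x %*% u
  dr <- rowSums(sm); dc <- colSums(sm)
  lw <- diag(rowSums(wm)) - wm
  term_s <- sum(p * (dr * p)) - 2 * sum(p * (sm %*% a)) + sum(a * (dc * a))
  term_w <- 2 * sum(p * (lw %*% p))
  term_pen <- lam * sum((sqrt(wm) - 1)^2)
  0.5 * (term_s + term_w + term_pen)
}

#' Closed-form update of the fused network given the projection
#'
#' For fixed U each pair decouples; minimizing
#' \eqn{w d_{ij}^2 + \lambda(\sqrt{w} - 1)^2} over w gives the global
#' minimizer \eqn{w_{ij} = (\lambda / (d_{ij}^2 + \lambda))^2} with
#' \eqn{d_{ij}^2 = \|(x_i - x_j)U\|^2}. Identical rows get weight 1; large
#' lambda pushes every weight towards 1. The diagonal is forced to zero
#' afterwards (no self-loops).
#'
#' @param u k x r projection.
#' @param target_feats n x k target features with gene rownames.
#' @param lam positive penalty weight.
#' @return a [weighted_network()] with entries in [0, 1].
#' @export
update_w <- function(u, target_feats, lam) {
  if (lam <= 0) stop("lambda must be positive", call. = FALSE)
  p <- target_feats %*% u
  d2 <- row_sqdist(p)
  w <- (lam / (d2 + lam))^2
  dimnames(w) <- list(rownames(target_feats), rownames(target_feats))
  weighted_network(w)
}

#' Gradient of the fusion objective with respect to U
#'
#' Analytic gradient of [objective_elementwise()]:
#' \eqn{X' D_r X U - X' S A + 2 X' L_W X U}, with D_r the row-degree
#' diagonal of S. The sign of the S-term follows from differentiating the
#' cross term \eqn{-2 tr(U'X'SA)} and is validated against central finite
#' differences in the test suite.
#'
#' @inheritParams objective_elementwise
#' @return k x r gradient matrix.
#' @export
grad_u <- function(u, w, s, target_feats, a) {
  wm <- as_matrix_w(w); sm <- as_matrix_s(s)
  x <- target_feats
  xu <- x %*% u
  dr <- rowSums(sm)
  lw <- diag(rowSums(wm)) - wm
  crossprod(x, dr * xu) - crossprod(x, sm %*% a) + 2 * crossprod(x, lw %*% xu)
}

#' One gradient step on the projection
#'
#' Plain descent step \eqn{U \leftarrow U - \alpha\,\nabla_U}; step-size
#' control (backtracking until the objective decreases) lives in
#' [fit_fusion()].
#'
#' @param u current projection.
#' @param grad gradient matrix of the same shape.
#' @param step positive step size.
#' @return updated projection.
#' @export
update_u <- function(u, grad, step) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  u - step * grad
}

#' Learn the fused gene network by alternating minimization
#'
#' Alternates the exact closed-form network update ([update_w()]) with
#' line-searched gradient descent on the projection U, starting U from the
#' top-r right singular directions of the target features (deterministic;
#' random initialization would hurt reproducibility). Each full sweep cannot
#' increase the objective: the W step is the per-pair global minimizer and
#' the U step is only accepted on decrease, so the recorded trace is
#' non-increasing. Stops when the relative objective change drops below
#' `tol` or after `max_iter` sweeps.
#'
#' @param target_feats n x k target feature matrix with gene rownames.
#' @param s affinity matrix (target rows x source columns).
#' @param a n x r source representation from [fit_lmnn()].
#' @param lam penalty weight lambda (default 1; accuracy is flat for lambda
#'   in roughly [0.01, 5] and degrades when the penalty dominates).
#' @param max_iter maximum sweeps (default 200).
#' @param tol relative objective-change stopping threshold (default 1e-5).
#' @param step_init initial gradient step (default 1e-2), adapted by
#'   backtracking.
#' @param seed reserved for degenerate SVD ties; the fit is deterministic.
#' @return list with `U`, `W` (a [weighted_network()]), `lambda`,
#'   `objective_trace` (one value per sweep), `iterations`, `converged`;
#'   class `"fusion_model"`.
#' @export
fit_fusion <- function(target_feats, s, a, lam = 1, max_iter = 200L,
                       tol = 1e-5, step_init = 1e-2, seed = 1L) {
  if (lam <= 0) stop("lambda must be positive", call. = FALSE)
  n <- nrow(target_feats); k <- ncol(target_feats); r <- ncol(a)
  sm <- as_matrix_s(s)
  if (nrow(sm) != n || ncol(sm) != n || nrow(a) != n)
    stop("shape mismatch between target features, affinity and representation",
         call. = FALSE)
  if (r > k) stop("representation dimension exceeds feature dimension", call. = FALSE)

  sv <- svd(target_feats, nu = 0L, nv = r)
  u <- fix_signs(matrix(0, 1L, r), sv$v)$loadings

  w <- update_w(u, target_feats, lam)
  obj <- objective_traceform(u, w, sm, target_feats, a, lam)
  if (!is.finite(obj)) stop("non-finite objective at initialization", call. = FALSE)
  trace <- numeric(0)
  step <- step_init
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- update_w(u, target_feats, lam)
    obj_w <- objective_traceform(u, w, sm, target_feats, a, lam)
    g <- grad_u(u, w, sm, target_feats, a)
    obj_u <- obj_w
    while (step >= 1e-12) {
      u_new <- update_u(u, g, step)
      cand <- objective_traceform(u_new, w, sm, target_feats, a, lam)
      if (is.finite(cand) && cand < obj_w) {
        u <- u_new; obj_u <- cand
        step <- step * 2
        break
      }
      step <- step / 2
    }
    if (!is.finite(obj_u))
      stop(sprintf("non-finite objective at iteration %d", it), call. = FALSE)
    trace <- c(trace, obj_u)
    rel <- abs(obj - obj_u) / max(abs(obj), 1e-12)
    obj <- obj_u
    if (rel < tol) { converged <- TRUE; break }
    if (step < 1e-12) { converged <- TRUE; break }  # stalled line search
  }
  w <- update_w(u, target_feats, lam)
  structure(list(U = u, W = w, lambda = lam, objective_trace = trace,
                 iterations = it, converged = converged),
            class = "fusion_model")
}
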