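# Shared fixture builders; everything is generated in code, seeded.

make_expr <- function(n = 4, d = 5, seed = 1, genes = NULL, samples = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(n * d), n, d)
  rownames(v) <- if (is.null(genes)) sprintf("g%02d", seq_len(n)) else genes
  colnames(v) <- if (is.null(samples)) sprintf("s%02d", seq_len(d)) else samples
  expression_matrix(v)
}

# Random shape-consistent instance for the fusion objective/gradient.
rand_instance <- function(n, k, r, seed, lam = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * k), n, k,
              dimnames = list(sprintf("g%02d", seq_len(n)), NULL))
  u <- matrix(rnorm(k * r), k, r)
  a <- matrix(rnorm(n * r), n, r)
  s <- matrix(runif(n * n), n, n)
  w0 <- matrix(runif(n * n), n, n)
  w <- (w0 + t(w0)) / 2
  diag(w) <- 0
  dimnames(w) <- list(rownames(x), rownames(x))
  list(x = x, u = u, a = a, s = s, w = w, lam = lam)
}

# Brute-force scalar-loop oracle for the fusion objective.
objective_loop_oracle <- function(u, w, s, x, a, lam) {
  n <- nrow(x)
  p <- x %*% u
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + s[i, j] * sum((p[i, ] - a[j, ])^2) +
        w[i, j] * sum((p[i, ] - p[j, ])^2) +
        lam * (sqrt(w[i, j]) - 1)^2
    }
  }
  acc / 2
}

# Central finite-difference gradient of the elementwise objective wrt U.
fd_grad_u <- function(u, w, s, x, a, lam, h = 1e-5) {
  g <- matrix(0, nrow(u), ncol(u))
  for (i in seq_len(nrow(u))) {
    for (j in seq_len(ncol(u))) {
      up <- u; up[i, j] <- up[i, j] + h
      um <- u; um[i, j] <- um[i, j] - h
      g[i, j] <- (objective_elementwise(up, w, s, x, a, lam) -
                    objective_elementwise(um, w, s, x, a, lam)) / (2 * h)
    }
  }
  g
}

# Random symmetric nonnegative network with gene ids.
rand_network <- function(n, seed, density = 0.3) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m))
  on <- sample(ut, max(1L, round(density * length(ut))))
  m[on] <- runif(length(on), 0.1, 1)
  m <- m + t(m)
  dimnames(m) <- list(sprintf("g%02d", seq_len(n)), sprintf("g%02d", seq_len(n)))
  weighted_network(m)
}
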