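test_that("symmetric normalization: closed form on regular graphs, zeros for isolates", {
  # 4-cycle: every node has degree 2
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[cbind(1:4, c(2, 3, 4, 1))] <- 1
  m <- m + t(m)
  w <- weighted_network(m)
  expect_lt(max(abs(normalize_network(w) - unclass(w) / 2)), 1e-12)

  # isolated node keeps zero row/column
  m2 <- rbind(cbind(m, e = 0), e = 0)
  colnames(m2) <- rownames(m2) <- c(letters[1:4], "e")
  nw <- normalize_network(weighted_network(m2))
  expect_identical(unname(nw["e", ]), rep(0, 5))

  # spectral radius bounded by 1 on random graphs
  for (seed in 1:5) {
    nw <- normalize_network(rand_network(15, seed))
    ev <- eigen(nw, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(abs(ev)), 1 + 1e-10)
  }
})

test_that("propagation fixed point matches the direct linear solve", {
  for (seed in 1:5) {
    w <- rand_network(30, seed)
    set.seed(seed)
    y <- runif(30); y[sample(30, 20)] <- 0
    alpha <- 0.9
    r <- prince_rank(w, y, alpha = alpha, tol = 1e-14)
    wn <- normalize_network(w)
    f_direct <- solve(diag(30) - alpha * wn, (1 - alpha) * (y / sum(y)))
    direct <- gene_ranking(rownames(w), f_direct + 1e-12)
    expect_identical(r$gene_id, direct$gene_id)
    expect_lt(max(abs(r$score - direct$score)) / max(direct$score), 1e-8)
  }
})

test_that("alpha -> 0 reduces propagation to the prior ordering", {
  w <- rand_network(12, seed = 3)
  set.seed(3)
  y <- runif(12)  # distinct prior values
  r <- prince_rank(w, y, alpha = 1e-8)
  expect_identical(r$gene_id, rownames(w)[order(-y, rownames(w), method = "radix")])
})

test_that("prior mass cannot leak across disconnected components", {
  m <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  m[1, 2] <- m[2, 3] <- m[4, 5] <- m[5, 6] <- 1
  m <- m + t(m)
  w <- weighted_network(m)
  y <- c(1, 0, 0, 0, 0, 0)
  r <- prince_rank(w, y, alpha = 0.9)
  sc <- setNames(r$score, r$gene_id)
  expect_lt(max(sc[c("d", "e", "f")]), 1e-11 + 1e-12)
  expect_gt(min(sc[c("a", "b", "c")]), 1e-6)
  expect_error(prince_rank(w, rep(0, 6)), "positive entry")
})

test_that("pagerank is uniform on a cycle and conserves probability", {
  m <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  m[cbind(1:5, c(2:5, 1))] <- 1
  m <- m + t(m)
  r <- pagerank_rank(weighted_network(m))
  expect_lt(max(abs(r$score - 0.2)), 1e-10)
  for (seed in 1:3) {
    r2 <- pagerank_rank(rand_network(20, seed))
    expect_lt(abs(sum(r2$score) - 1), 1e-10)
  }
})

test_that("pagerank matches the stationary linear system on a path graph", {
  m <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m[1, 2] <- m[2, 3] <- 1
  m <- m + t(m)
  d <- 0.85
  p <- sweep(m, 2, colSums(m), "/")
  v <- solve(diag(3) - d * p, (1 - d) * rep(1 / 3, 3))
  r <- pagerank_rank(weighted_network(m), damping = d, tol = 1e-14)
  expect_lt(max(abs(setNames(r$score, r$gene_id)[c("a", "b", "c")] - v)), 1e-8)
})

test_that("source labels convert to a normalized prior", {
  y <- pathogenic_labels(setNames(c(1L, 0L, 1L, rep(0L, 7)), sprintf("g%02d", 1:10)))
  pr <- build_prior_from_source(y)
  expect_identical(unname(pr[c("g01", "g03")]), c(0.5, 0.5))
  expect_equal(sum(pr), 1)
  # degenerate all-pathogenic vector (plain input): uniform prior
  all1 <- setNames(rep(1, 4), letters[1:4])
  expect_identical(unname(build_prior_from_source(all1)), rep(0.25, 4))
  expect_error(build_prior_from_source(setNames(rep(0, 4), letters[1:4])),
               "no pathogenic")
})

test_that("adding weight on a prior-adjacent edge does not hurt the neighbor", {
  w <- rand_network(10, seed = 6)
  y <- c(1, rep(0, 9))
  base <- prince_rank(w, y, alpha = 0.8, tol = 1e-14)
  m <- unclass(w)
  m[1, 2] <- m[2, 1] <- m[1, 2] + 2
  boosted <- prince_rank(weighted_network(m), y, alpha = 0.8, tol = 1e-14)
  g2 <- rownames(m)[2]
  expect_gte(setNames(boosted$score, boosted$gene_id)[g2] + 1e-12,
             setNames(base$score, base$gene_id)[g2])
})
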