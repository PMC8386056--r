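test_that("elementwise objective matches a brute-force scalar loop", {
  for (seed in 1:3) {
    inst <- rand_instance(5, 4, 2, seed)
    expect_equal(objective_elementwise(inst$u, inst$w, inst$s, inst$x, inst$a, inst$lam),
                 objective_loop_oracle(inst$u, inst$w, inst$s, inst$x, inst$a, inst$lam),
                 tolerance = 1e-10)
  }
})

test_that("closed-form corner cases of the objective hold", {
  n <- 4; k <- 3; r <- 2
  x <- matrix(1, n, k)  # identical rows => all projected rows identical
  w1 <- matrix(1, n, n)
  s0 <- matrix(0, n, n)
  u <- matrix(rnorm(k * r), k, r)
  expect_equal(objective_elementwise(u, w1, s0, x, matrix(0, n, r), 1), 0)
  # W = 0, S = 0: only the penalty survives, Phi(0) = 1 on all n^2 pairs
  lam <- 2.5
  expect_equal(objective_elementwise(u, matrix(0, n, n), s0, x, matrix(0, n, r), lam),
               0.5 * n^2 * lam)
  expect_error(objective_elementwise(u, w1, s0, x, matrix(0, n, r), 0), "lambda")
})

test_that("trace form equals the elementwise form", {
  for (seed in 1:5) {
    inst <- rand_instance(5, 4, 3, seed, lam = runif(1, 0.1, 5))
    e <- objective_elementwise(inst$u, inst$w, inst$s, inst$x, inst$a, inst$lam)
    t <- objective_traceform(inst$u, inst$w, inst$s, inst$x, inst$a, inst$lam)
    expect_equal(t, e, tolerance = 1e-8)
    # S = 0 kills the affinity terms in both forms
    s0 <- matrix(0, 5, 5)
    expect_equal(objective_traceform(inst$u, inst$w, s0, inst$x, inst$a, inst$lam),
                 objective_elementwise(inst$u, inst$w, s0, inst$x, inst$a, inst$lam),
                 tolerance = 1e-8)
  }
})

test_that("update_w is the per-pair closed-form minimizer", {
  inst <- rand_instance(6, 4, 2, seed = 2)
  x <- inst$x
  x[2, ] <- x[1, ]  # identical rows -> distance 0 -> weight 1 (then diag rule)
  w <- update_w(inst$u, x, lam = 1)
  expect_equal(unclass(w)[1, 2], 1)
  expect_identical(diag(unclass(w)), setNames(rep(0, 6), rownames(x)))
  expect_true(all(unclass(w) >= 0 & unclass(w) <= 1))
  expect_lt(max(abs(unclass(w) - t(unclass(w)))), 1e-12)

  # lambda = 1, d^2 = 1: w = 0.25, confirmed by a scalar grid oracle
  grid <- seq(0, 1, length.out = 10001)
  vals <- grid * 1 + (sqrt(grid) - 1)^2
  expect_equal((1 / (1 + 1))^2, 0.25)
  expect_equal(grid[which.min(vals)], 0.25, tolerance = 2e-4)

  # weights increase monotonically towards 1 as lambda grows
  lams <- c(0.1, 1, 10, 1e6)
  w_seq <- vapply(lams, function(l) unclass(update_w(inst$u, inst$x, l))[1, 3],
                  numeric(1))
  expect_true(all(diff(w_seq) > 0))
  expect_gt(w_seq[4], 0.999)
})

test_that("grad_u matches central finite differences and vanishes when it must", {
  inst <- rand_instance(8, 4, 3, seed = 5)
  g <- grad_u(inst$u, inst$w, inst$s, inst$x, inst$a)
  fd <- fd_grad_u(inst$u, inst$w, inst$s, inst$x, inst$a, inst$lam)
  expect_lt(sqrt(sum((g - fd)^2)) / sqrt(sum(fd^2)), 1e-5)

  z <- matrix(0, 8, 8)
  g0 <- grad_u(inst$u, z, z, inst$x, inst$a)
  expect_identical(max(abs(g0)), 0)
})

test_that("update_u is a plain descent step that solves a quadratic toy exactly", {
  u <- matrix(rnorm(6), 3, 2)
  expect_identical(update_u(u, matrix(0, 3, 2), 0.1), u)
  expect_error(update_u(u, u, 0), "step")
  # 1-parameter quadratic f(t) = (t - 3)^2, gradient 2(t - 3)
  t <- 0
  for (i in 1:200) t <- update_u(matrix(t), matrix(2 * (t - 3)), 0.25)[1, 1]
  expect_equal(t, 3, tolerance = 1e-6)
})

test_that("alternating fit decreases the objective monotonically", {
  for (seed in 1:3) {
    inst <- rand_instance(20, 6, 3, seed)
    fm <- fit_fusion(inst$x, inst$s, inst$a, lam = 1, max_iter = 50)
    tr <- fm$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
    expect_true(all(unclass(fm$W) >= 0 & unclass(fm$W) <= 1))
    expect_lt(max(abs(unclass(fm$W) - t(unclass(fm$W)))), 1e-12)
  }
})

test_that("extreme lambda saturates the fitted network at 1", {
  inst <- rand_instance(15, 5, 3, seed = 9)
  fm <- fit_fusion(inst$x, inst$s, inst$a, lam = 1e9, max_iter = 20)
  off <- unclass(fm$W)[upper.tri(unclass(fm$W))]
  expect_true(all(off >= 0.999))
})

test_that("identical target rows keep weight 1 throughout the fit", {
  inst <- rand_instance(12, 5, 3, seed = 11)
  x <- inst$x
  x[7, ] <- x[3, ]
  fm <- fit_fusion(x, inst$s, inst$a, lam = 1, max_iter = 30)
  expect_equal(unclass(fm$W)[3, 7], 1)
})
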