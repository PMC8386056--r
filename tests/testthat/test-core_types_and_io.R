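test_that("expression TSV round-trips exactly on ids and to 1e-12 on values", {
  x <- make_expr(3, 4, seed = 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, f)
  y <- read_expression(f)
  expect_identical(rownames(y), rownames(x))
  expect_identical(colnames(y), colnames(x))
  expect_lt(max(abs(unclass(y) - unclass(x))), 1e-12)
})

test_that("malformed expression input is rejected with a located error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2\ts3",
               "gA\t1\t2\t3", "gB\t4\t5\t6", "gA\t7\t8\t9"), f)
  expect_error(read_expression(f), "gA")

  writeLines(c("gene_id\ts1\ts2\ts3",
               "gA\t1\tNA\t3", "gB\t4\t5\t6"), f)
  expect_error(read_expression(f), "gA.*s2")

  writeLines(c("gene_id\ts1\ts2\ts3",
               "gA\t1\t2\t3", "gB\t4\toops\t6"), f)
  expect_error(read_expression(f), "gB.*s2")
})

test_that("expression matrix invariants are enforced", {
  v <- matrix(1:6, 2, 3)
  expect_error(expression_matrix(v), "rownames")
  dimnames(v) <- list(c("a", "b"), c("s1", "s2", "s3"))
  expect_silent(expression_matrix(v))
  expect_error(expression_matrix(v[, 1:2, drop = FALSE]), "3 samples")
  v[1, 1] <- NA
  expect_error(expression_matrix(v), "missing value")
})

test_that("align_gene_universe intersects in source order and is idempotent", {
  src <- make_expr(3, 4, genes = c("g1", "g2", "g3"))
  tgt <- make_expr(3, 5, seed = 2, genes = c("g2", "g3", "g4"))
  lab <- pathogenic_labels(c(g1 = 0L, g2 = 1L, g3 = 0L))
  suppressMessages(al <- align_gene_universe(src, tgt, lab))
  expect_identical(rownames(al$source), c("g2", "g3"))
  expect_identical(rownames(al$target), c("g2", "g3"))
  expect_identical(as.integer(unclass(al$labels)), c(1L, 0L))

  # identical universes: unchanged
  al2 <- align_gene_universe(al$source, al$target, al$labels)
  expect_identical(unclass(al2$source), unclass(al$source))
  expect_identical(unclass(al2$labels), unclass(al$labels))

  # disjoint: hard error
  tgt2 <- make_expr(2, 5, genes = c("x1", "x2"))
  expect_error(align_gene_universe(src, tgt2, lab), "no gene identifiers")
})

test_that("weighted_network enforces symmetry, nonnegativity and zero diagonal", {
  m <- matrix(c(1, 2, 2, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  w <- weighted_network(m)
  expect_identical(diag(unclass(w)), c(a = 0, b = 0))
  m2 <- m; m2[1, 2] <- 5
  expect_error(weighted_network(m2), "symmetric")
  m3 <- m; m3[1, 2] <- m3[2, 1] <- -1
  expect_error(weighted_network(m3), "nonnegative")
})

test_that("Laplacian rows sum to zero and it is positive semidefinite", {
  for (seed in 1:5) {
    w <- rand_network(12, seed)
    l <- network_laplacian(w)
    expect_lt(max(abs(rowSums(l))), 1e-10)
    expect_gt(min(eigen(l, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("network edge lists round-trip", {
  w <- rand_network(8, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(w, f)
  w2 <- read_network(f, universe = rownames(w))
  expect_lt(max(abs(unclass(w2) - unclass(w))), 1e-12)
})

test_that("rankings are sorted, positive, deterministic on ties, and round-trip", {
  r <- gene_ranking(c("b", "a", "c"), c(1, 2, 1))
  expect_identical(r$gene_id, c("a", "b", "c"))  # tie between b,c broken by id
  expect_identical(r$rank, 1:3)
  expect_error(gene_ranking(c("a"), 0), "positive")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(r, f)
  r2 <- read_ranking(f)
  expect_identical(r2$gene_id, r$gene_id)
  expect_lt(max(abs(r2$score - r$score)), 1e-12)

  # empty ranking -> header-only file
  write_ranking(gene_ranking(character(0), numeric(0)), f)
  expect_identical(length(readLines(f)), 1L)
})

test_that("gene lists honor comments and pathogenic labels need both classes", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# known drivers", "g2", "g3  ", "", "# end"), f)
  expect_identical(read_gene_list(f), c("g2", "g3"))
  lab <- pathogenic_labels(read_gene_list(f), gene_ids = c("g1", "g2", "g3"))
  expect_identical(as.integer(lab), c(0L, 1L, 1L))
  expect_error(pathogenic_labels(c(a = 1L, b = 1L)), "both classes")
  expect_error(pathogenic_labels(c(a = 0L, b = 0L)), "both classes")
})
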