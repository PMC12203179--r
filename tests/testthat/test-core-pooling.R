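test_that("strip_special_tokens keeps residue rows/columns jointly", {
  set.seed(11)
  mats <- replicate(2, matrix(runif(16), 4, 4), simplify = FALSE)
  mask <- c(TRUE, FALSE, FALSE, TRUE)
  stack <- attention_stack(mats, 2, 1, special_mask = mask)
  emb <- token_embeddings(matrix(rnorm(12), 4, 3), special_mask = mask)
  out <- strip_special_tokens(stack, emb)
  expect_equal(out$stack$n_tokens, 2L)
  expect_equal(out$emb$values, emb$values[2:3, ])
  # attention entry (1,2) of output = entry (2,3) of each input restriction
  for (i in 1:2)
    expect_identical(out$stack$matrices[[i]][1, 2], mats[[i]][2, 3])

  # all-residue mask: identity
  stack0 <- attention_stack(mats, 2, 1)
  emb0 <- token_embeddings(emb$values)
  out0 <- strip_special_tokens(stack0, emb0)
  expect_identical(out0$stack$matrices, mats)

  # degenerate / mismatched masks
  allspec <- attention_stack(mats, 2, 1, special_mask = rep(TRUE, 4))
  embspec <- token_embeddings(emb$values, special_mask = rep(TRUE, 4))
  expect_error(strip_special_tokens(allspec, embspec), "no residue")
  expect_error(strip_special_tokens(stack0, emb), "mask mismatch")
})

test_that("max pooling is the pixelwise maximum over all matrices", {
  m1 <- matrix(c(0.9, 0.3, 0.1, 0.7), 2, 2, byrow = FALSE)
  m2 <- matrix(c(0.2, 0.6, 0.8, 0.4), 2, 2, byrow = FALSE)
  stack <- attention_stack(list(m1, m2), 2, 1)
  expect_equal(max_pool_attention(stack)$matrix,
               matrix(c(0.9, 0.6, 0.8, 0.7), 2, 2))
  # single matrix and elementwise-dominant matrix
  expect_equal(max_pool_attention(attention_stack(list(m1), 1, 1))$matrix, m1)
  big <- m1 + 1
  expect_equal(max_pool_attention(attention_stack(list(big, m1), 2, 1))$matrix,
               big)
  expect_error(attention_stack(list(m1, matrix(0, 3, 3)), 2, 1), "expected")
})

test_that("token graph copies weights and flags dangling rows", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  g <- build_token_graph(structure(list(matrix = W, n_residues = 2),
                                   class = "pooled_attention"))
  expect_identical(g$W, W)
  expect_false(any(g$dangling))
  W2 <- rbind(c(0, 0, 0), c(1, 0.5, 0), c(0, 0.2, 0.3))
  g2 <- build_token_graph(W2)
  expect_identical(g2$dangling, c(TRUE, FALSE, FALSE))
  # self-loops retained by default, droppable by flag
  expect_gt(build_token_graph(W2)$W[3, 3], 0)
  expect_equal(build_token_graph(W2, drop_self_loops = TRUE)$W[3, 3], 0)
})

test_that("PageRank matches hand-solved and symmetric cases", {
  # symmetric graph -> uniform
  g <- build_token_graph(matrix(1, 4, 4))
  expect_equal(pagerank_importance(g)$weights, rep(0.25, 4))
  # teleport-only limit
  gr <- build_token_graph(matrix(runif(9), 3, 3))
  expect_equal(pagerank_importance(gr, pagerank_config(damping = 0))$weights,
               rep(1 / 3, 3))
  # 2x2 stationarity system solved by hand: r1 = 0.5/1.425
  W <- matrix(c(0, 0.5, 1, 0.5), 2, 2)
  a <- pagerank_importance(build_token_graph(W),
                           pagerank_config(tolerance = 1e-13,
                                           max_iterations = 2000))
  expect_equal(a$weights, c(0.5 / 1.425, 0.925 / 1.425), tolerance = 1e-9)
  expect_equal(sum(a$weights), 1, tolerance = 1e-12)
})

test_that("PageRank agrees with the dense eigenvector oracle and igraph", {
  set.seed(42)
  W <- matrix(runif(36), 6, 6)
  mine <- pagerank_importance(build_token_graph(W),
                              pagerank_config(tolerance = 1e-14,
                                              max_iterations = 5000))
  expect_lt(sum(abs(mine$weights - dense_pagerank_oracle(W))), 1e-8)
  skip_if_not_installed("igraph")
  gi <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                            weighted = TRUE, diag = TRUE)
  pr <- igraph::page_rank(gi, damping = 0.85,
                          weights = igraph::E(gi)$weight)$vector
  expect_lt(sum(abs(mine$weights - pr)), 1e-6)
})

test_that("PageRank non-convergence policy is honored", {
  W <- matrix(runif(100), 10, 10)
  cfg_fail <- pagerank_config(tolerance = 1e-16, max_iterations = 2L)
  expect_error(pagerank_importance(build_token_graph(W), cfg_fail),
               "did not converge in 2 iterations")
  cfg_last <- pagerank_config(tolerance = 1e-16, max_iterations = 2L,
                              on_nonconvergence = "return-last")
  expect_warning(a <- pagerank_importance(build_token_graph(W), cfg_last),
                 "did not converge")
  expect_equal(sum(a$weights), 1, tolerance = 1e-12)
  expect_false(a$converged)
})

test_that("normalize_importance divides by the total and is idempotent", {
  expect_equal(normalize_importance(c(2, 2))$weights, c(0.5, 0.5))
  expect_equal(normalize_importance(c(1, 3))$weights, c(0.25, 0.75))
  expect_equal(normalize_importance(c(0.25, 0.75))$weights, c(0.25, 0.75))
  expect_error(normalize_importance(c(0, 0)), "all-zero")
  expect_error(normalize_importance(c(-1, 2)), "nonnegative")
})

test_that("pool_embeddings is the importance-weighted row sum", {
  E <- rbind(c(0, 4), c(4, 0))
  expect_equal(pool_embeddings(E, c(0.5, 0.5))$vector, c(2, 2))
  expect_equal(pool_embeddings(E, c(0.25, 0.75))$vector, c(3, 1))
  expect_equal(pool_embeddings(E, c(0, 1))$vector, c(4, 0))
  expect_error(pool_embeddings(E, c(1, 0, 0)), "differ")
})

test_that("uniform attention reduces the pipeline to mean pooling", {
  set.seed(5)
  n <- 12
  mats <- replicate(6, matrix(1 / n, n, n), simplify = FALSE)
  stack <- attention_stack(mats, 3, 2, row_stochastic = TRUE)
  emb <- token_embeddings(matrix(rnorm(n * 7), n, 7))
  res <- pool_parti(stack, emb)
  expect_equal(res$importance$weights, rep(1 / n, n), tolerance = 1e-9)
  expect_equal(res$embedding$vector, baseline_pool(emb, "mean")$vector,
               tolerance = 1e-9)
})

test_that("pipeline is equivariant under token permutation", {
  set.seed(99)
  for (rep in 1:5) {
    fx <- random_fixture(n = 15, n_special = 2)
    res <- pool_parti(fx$stack, fx$emb)
    perm <- sample(15)
    stack_p <- attention_stack(
      lapply(fx$stack$matrices, function(m) m[perm, perm]),
      fx$stack$n_layers, fx$stack$n_heads,
      special_mask = fx$stack$special_mask[perm])
    emb_p <- token_embeddings(fx$emb$values[perm, ],
                              special_mask = fx$emb$special_mask[perm])
    res_p <- pool_parti(stack_p, emb_p)
    expect_equal(res_p$embedding$vector, res$embedding$vector,
                 tolerance = 1e-12)
    # importance follows the residue-order permutation
    keep <- !fx$stack$special_mask
    orig_ids <- which(keep)
    perm_ids <- perm[!fx$stack$special_mask[perm]]
    expect_equal(res_p$importance$weights,
                 res$importance$weights[match(perm_ids, orig_ids)],
                 tolerance = 1e-12)
  }
})

test_that("embedding scale does not grow with sequence length", {
  row <- rnorm(8)
  norms <- sapply(c(10, 100, 400), function(n) {
    mats <- replicate(2, matrix(1 / n, n, n), simplify = FALSE)
    stack <- attention_stack(mats, 2, 1)
    emb <- token_embeddings(matrix(rep(row, each = n), n, 8))
    sqrt(sum(pool_parti(stack, emb)$embedding$vector^2))
  })
  expect_equal(norms[1], norms[3], tolerance = 1e-9)
  # contrast: sum pooling grows linearly
  sums <- sapply(c(10, 100), function(n) {
    emb <- token_embeddings(matrix(rep(row, each = n), n, 8))
    sqrt(sum(baseline_pool(emb, "sum")$vector^2))
  })
  expect_equal(sums[2] / sums[1], 10, tolerance = 1e-9)
})

test_that("baseline poolers follow their definitions", {
  E <- rbind(c(1, 3), c(3, 1))
  emb <- token_embeddings(E)
  expect_equal(baseline_pool(emb, "mean")$vector, c(2, 2))
  expect_equal(baseline_pool(emb, "max")$vector, c(3, 3))
  expect_equal(baseline_pool(emb, "sum")$vector, c(4, 4))
  one <- token_embeddings(matrix(c(5, -2), 1, 2))
  for (m in c("mean", "max", "sum"))
    expect_equal(baseline_pool(one, m)$vector, c(5, -2))
  cls <- token_embeddings(rbind(c(9, 9), E),
                          special_mask = c(TRUE, FALSE, FALSE))
  expect_equal(baseline_pool(cls, "cls")$vector, c(9, 9))
  expect_equal(baseline_pool(cls, "mean")$vector, c(2, 2))  # specials excluded
  expect_error(baseline_pool(emb, "cls"), "no special token")
})

test_that("row-stochastic validation flags bad stacks", {
  good <- matrix(c(0.3, 0.5, 0.7, 0.5), 2, 2)
  expect_silent(attention_stack(list(good), 1, 1, row_stochastic = TRUE))
  bad <- matrix(c(0.3, 0.5, 0.9, 0.5), 2, 2)
  expect_error(attention_stack(list(bad), 1, 1, row_stochastic = TRUE),
               "row-stochastic")
  expect_error(attention_stack(list(-good), 1, 1), "negative")
  expect_error(attention_stack(list(), 0, 0), "at least one")
})
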