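# Independent oracles used to cross-check package implementations.
# These deliberately take the brute-force route (dense solves, loops,
# exhaustive enumeration) and share no code with the package internals.

# Principal-eigenvector solve of the explicitly formed Google matrix.
dense_pagerank_oracle <- function(W, damping = 0.85) {
  n <- nrow(W)
  out <- rowSums(W)
  P <- W
  P[out > 0, ] <- P[out > 0, , drop = FALSE] / out[out > 0]
  P[out == 0, ] <- 1 / n
  G <- damping * P + (1 - damping) / n
  e <- eigen(t(G))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# Loop-based cosine retrieval oracle (no matrix algebra, no shared code).
oracle_cosine <- function(x, y) {
  s <- 0; nx <- 0; ny <- 0
  for (k in seq_along(x)) {
    s <- s + x[k] * y[k]; nx <- nx + x[k]^2; ny <- ny + y[k]^2
  }
  s / (sqrt(nx) * sqrt(ny))
}

oracle_neighbor_order <- function(ids, emb, qid) {
  qi <- which(ids == qid)
  others <- setdiff(seq_along(ids), qi)
  sims <- sapply(others, function(j) oracle_cosine(emb[qi, ], emb[j, ]))
  others[order(-sims, ids[others])]
}

oracle_precision <- function(ids, emb, labels, qid, fraction = 0.10) {
  qi <- which(ids == qid)
  m_c <- sum(labels == labels[qi])
  r <- max(1, ceiling(fraction * m_c))
  ord <- oracle_neighbor_order(ids, emb, qid)
  hits <- 0
  for (j in ord[seq_len(r)]) if (labels[j] == labels[qi]) hits <- hits + 1
  hits / r
}

oracle_mrr <- function(ids, emb, labels, qids) {
  rr <- sapply(qids, function(qid) {
    qi <- which(ids == qid)
    ord <- oracle_neighbor_order(ids, emb, qid)
    rank <- which(labels[ord] == labels[qi])[1]
    1 / rank
  })
  mean(rr)
}

# Exhaustive enumeration of E[Jaccard] over all pairs of m-subsets of n.
enum_expected_jaccard <- function(n, m) {
  subsets <- utils::combn(n, m)
  M <- matrix(0L, ncol(subsets), n)
  for (s in seq_len(ncol(subsets))) M[s, subsets[, s]] <- 1L
  X <- M %*% t(M)                        # pairwise intersection sizes
  mean(X / (2 * m - X))
}

# Random small weighted digraph with occasional zero rows (dangling nodes).
random_digraph <- function(n, zero_row_prob = 0.15) {
  W <- matrix(stats::runif(n * n), n, n) *
    matrix(stats::rbinom(n * n, 1, 0.7), n, n)
  for (i in seq_len(n)) if (stats::runif(1) < zero_row_prob) W[i, ] <- 0
  W
}

# Random attention stack + embeddings for pipeline property tests.
random_fixture <- function(n = 20, L = 2, H = 2, d = 5, n_special = 0) {
  mask <- rep(FALSE, n)
  if (n_special > 0) mask[c(1, n)] <- TRUE
  sp <- fixture_spec(n_tokens = n, n_layers = L, n_heads = H,
                     hub_indices = sample.int(n, 1), seed = sample.int(1e6, 1))
  stack0 <- gen_attention_stack(sp)
  stack <- attention_stack(stack0$matrices, L, H, special_mask = mask)
  emb <- token_embeddings(matrix(stats::rnorm(n * d), n, d),
                          special_mask = mask)
  list(stack = stack, emb = emb)
}

# Minimal single-chain PDB text (CA atoms only), residues first..last.
write_toy_pdb <- function(path, first = 10, last = 20, chain = "A",
                          b = 20.0) {
  lines <- character(0)
  serial <- 0
  for (r in first:last) {
    serial <- serial + 1
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      serial, chain, r, r * 1.5, 0, 0, 1.00, b))
  }
  writeLines(c(lines, "END"), path)
  path
}
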