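#' Drop special tokens from a paired attention stack and embedding matrix
#'
#' Encoder models prepend/append non-residue tokens (CLS/BOS, SEP/EOS,
#' padding). Importance and pooling are defined over residues only, so both
#' inputs are restricted jointly to the positions where `special_mask` is
#' `FALSE`; attention matrices are subset on rows and columns.
#'
#' @param stack an [attention_stack()].
#' @param emb the paired [token_embeddings()]; masks must be identical.
#' @return list with elements `stack` and `emb`, both restricted to residues.
#' @export
strip_special_tokens <- function(stack, emb) {
  stopifnot(inherits(stack, "attention_stack"),
            inherits(emb, "token_embeddings"))
  if (!identical(stack$special_mask, emb$special_mask))
    stop("special_mask mismatch between attention stack and token embeddings")
  keep <- !stack$special_mask
  if (!any(keep)) stop("no residue tokens remain after masking")
  if (all(keep)) return(list(stack = stack, emb = emb))
  mats <- lapply(stack$matrices, function(m) m[keep, keep, drop = FALSE])
  list(
    stack = attention_stack(mats, stack$n_layers, stack$n_heads,
                            special_mask = rep(FALSE, sum(keep))),
    emb = token_embeddings(emb$values[keep, , drop = FALSE],
                           special_mask = rep(FALSE, sum(keep))))
}

#' Pixelwise max pooling of an attention stack
#'
#' Collapses all L*H attention matrices into one n x n matrix whose (i, j)
#' entry is the maximum attention from query i to key j seen anywhere in the
#' model, capturing the strongest pairwise relationships across all layers
#' and heads.
#'
#' @param stack an [attention_stack()] (typically already restricted to
#'   residues).
#' @param head_average if `TRUE`, average heads within each layer first and
#'   max-pool across layers only. Default `FALSE` (max over all L*H matrices).
#' @return object of class `pooled_attention` with fields `matrix` and
#'   `n_residues`.
#' @export
max_pool_attention <- function(stack, head_average = FALSE) {
  stopifnot(inherits(stack, "attention_stack"))
  mats <- stack$matrices
  if (head_average && stack$n_heads > 1L) {
    mats <- lapply(seq_len(stack$n_layers), function(l) {
      idx <- (l - 1L) * stack$n_heads + seq_len(stack$n_heads)
      Reduce(`+`, stack$matrices[idx]) / stack$n_heads
    })
  }
  pooled <- mats[[1L]]
  for (m in mats[-1L]) pooled <- pmax(pooled, m)
  structure(list(matrix = pooled, n_residues = nrow(pooled)),
            class = "pooled_attention")
}

#' Interpret pooled attention as a directed weighted token graph
#'
#' The pooled matrix is treated as an adjacency matrix: node i is the i-th
#' retained token and the directed edge i -> j (query to key) carries weight
#' `W[i, j]`. Attention self-loops (diagonal) are kept by default; rows with
#' no positive out-weight are flagged dangling.
#'
#' @param pooled a `pooled_attention` (or a plain nonnegative square matrix).
#' @param drop_self_loops if `TRUE`, zero the diagonal before building.
#' @return object of class `token_graph` with fields `W`, `n_nodes`,
#'   `dangling` (logical per node).
#' @export
build_token_graph <- function(pooled, drop_self_loops = FALSE) {
  W <- if (inherits(pooled, "pooled_attention")) pooled$matrix else pooled
  if (!is.matrix(W) || nrow(W) != ncol(W) || any(W < 0))
    stop("pooled attention must be a nonnegative square matrix")
  if (drop_self_loops) diag(W) <- 0
  structure(list(W = W, n_nodes = nrow(W), dangling = rowSums(W) == 0),
            class = "token_graph")
}

#' Weighted PageRank token importance
#'
#' Computes the stationary distribution of the damped random surfer on the
#' weighted digraph by power iteration: out-weights of each node are
#' row-normalized into transition probabilities, the mass of dangling nodes
#' is redistributed uniformly, and the iterate is updated as
#' `r <- damping * (t(P) %*% r + dangling_mass / n) + (1 - damping) / n`,
#' starting from the uniform vector. Iteration stops when the L1 change is
#' below `n * tolerance`.
#'
#' @param graph a [build_token_graph()] result.
#' @param config a [pagerank_config()].
#' @return object of class `importance_vector`: list with `weights`
#'   (nonnegative, sums to 1), `n_residues`, `iterations`, `converged`.
#' @export
pagerank_importance <- function(graph, config = pagerank_config()) {
  stopifnot(inherits(graph, "token_graph"), inherits(config, "pagerank_config"))
  n <- graph$n_nodes
  if (n < 1L) stop("graph must have at least one node")
  W <- graph$W
  out <- rowSums(W)
  dangling <- out == 0
  P <- W
  pos <- !dangling
  P[pos, ] <- P[pos, , drop = FALSE] / out[pos]
  tP <- t(P)
  d <- config$damping
  r <- rep(1 / n, n)
  converged <- FALSE
  iter <- 0L
  delta <- NA_real_
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    dmass <- if (any(dangling)) sum(r[dangling]) else 0
    r_new <- d * (as.vector(tP %*% r) + dmass / n) + (1 - d) / n
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta < n * config$tolerance) { converged <- TRUE; break }
  }
  if (!converged) {
    msg <- sprintf(
      "PageRank did not converge in %d iterations (L1 residual %.3g, threshold %.3g)",
      iter, delta, n * config$tolerance)
    if (config$on_nonconvergence == "fail") stop(msg)
    warning(msg, call. = FALSE)
  }
  importance_vector(r / sum(r), iterations = iter, converged = converged)
}

#' Construct an importance vector
#'
#' @param weights nonnegative numeric vector summing to 1 within 1e-9.
#' @param iterations,converged optional PageRank diagnostics.
#' @return object of class `importance_vector`.
#' @export
importance_vector <- function(weights, iterations = NA_integer_,
                              converged = NA) {
  if (any(weights < 0) || anyNA(weights))
    stop("importance weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("importance weights must sum to 1 within 1e-9")
  structure(list(weights = as.numeric(weights),
                 n_residues = length(weights),
                 iterations = iterations, converged = converged),
            class = "importance_vector")
}

#' Normalize a raw nonnegative weight vector to sum to one
#'
#' Applied after PageRank as a guard against accumulated floating-point error
#' (the PageRank output already sums to one up to roundoff); idempotent.
#'
#' @param raw nonnegative numeric vector (or an `importance_vector`).
#' @return an `importance_vector`.
#' @export
normalize_importance <- function(raw) {
  w <- if (inherits(raw, "importance_vector")) raw$weights else raw
  if (any(w < 0) || anyNA(w)) stop("weights must be nonnegative")
  s <- sum(w)
  if (s == 0) stop("cannot normalize an all-zero weight vector")
  importance_vector(w / s)
}

#' Importance-weighted pooling of residue embeddings
#'
#' `E_seq = sum_i alpha_i * E_tok[i, ]`. Because the weights sum to one, the
#' scale of the result does not grow with sequence length.
#'
#' @param emb a [token_embeddings()] restricted to residues (or an n x d
#'   matrix).
#' @param alpha an `importance_vector` of matching length.
#' @return object of class `sequence_embedding`: list with `vector` and
#'   `pooling_method = "parti"`.
#' @export
pool_embeddings <- function(emb, alpha) {
  E <- if (inherits(emb, "token_embeddings")) emb$values else emb
  w <- if (inherits(alpha, "importance_vector")) alpha$weights else alpha
  if (nrow(E) != length(w))
    stop(sprintf("embedding rows (%d) and importance length (%d) differ",
                 nrow(E), length(w)))
  sequence_embedding(as.vector(crossprod(E, w)), "parti")
}

sequence_embedding <- function(vector, method) {
  if (any(!is.finite(vector))) stop("sequence embedding must be finite")
  structure(list(vector = as.numeric(vector), pooling_method = method),
            class = "sequence_embedding")
}

#' Pool PaRTI: attention-graph PageRank pooling of one protein
#'
#' Runs the full pipeline: special tokens are dropped, all attention matrices
#' are pixelwise max-pooled, the pooled matrix is read as a directed weighted
#' graph (query -> key), PageRank gives per-residue importance, the weights
#' are renormalized, and the sequence embedding is the importance-weighted
#' sum of residue embeddings. Fully deterministic given inputs and config.
#'
#' @inheritParams strip_special_tokens
#' @param config a [pagerank_config()].
#' @param head_average see [max_pool_attention()].
#' @param drop_self_loops see [build_token_graph()].
#' @return list with `embedding` (a `sequence_embedding`) and `importance`
#'   (an `importance_vector` over residues).
#' @examples
#' mats <- replicate(2, matrix(1 / 3, 3, 3), simplify = FALSE)
#' st <- attention_stack(mats, n_layers = 2, n_heads = 1)
#' em <- token_embeddings(matrix(rnorm(9), 3, 3))
#' res <- pool_parti(st, em)
#' res$importance$weights  # uniform: 1/3 each
#' @export
pool_parti <- function(stack, emb, config = pagerank_config(),
                       head_average = FALSE, drop_self_loops = FALSE) {
  stripped <- strip_special_tokens(stack, emb)
  pooled <- max_pool_attention(stripped$stack, head_average = head_average)
  graph <- build_token_graph(pooled, drop_self_loops = drop_self_loops)
  alpha <- normalize_importance(pagerank_importance(graph, config))
  list(embedding = pool_embeddings(stripped$emb, alpha),
       importance = alpha)
}

#' Baseline parameter-free poolers
#'
#' The four traditional parameter-free sequence poolers: per-dimension mean,
#' max and sum over residue rows (special tokens excluded), and the CLS
#' baseline returning the embedding row of the beginning-of-sequence token
#' (the first `TRUE` position of the special mask).
#'
#' @param emb a [token_embeddings()].
#' @param method one of `"mean"`, `"max"`, `"sum"`, `"cls"`.
#' @return a `sequence_embedding`.
#' @export
baseline_pool <- function(emb, method = c("mean", "max", "sum", "cls")) {
  method <- match.arg(method)
  stopifnot(inherits(emb, "token_embeddings"))
  if (method == "cls") {
    idx <- which(emb$special_mask)
    if (length(idx) == 0L)
      stop("cls pooling requested but no special token is present")
    return(sequence_embedding(emb$values[idx[1L], ], "cls"))
  }
  E <- emb$values[!emb$special_mask, , drop = FALSE]
  if (nrow(E) == 0L) stop("no residue rows to pool")
  v <- switch(method,
              mean = colMeans(E),
              max  = apply(E, 2L, max),
              sum  = colSums(E))
  sequence_embedding(v, method)
}
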