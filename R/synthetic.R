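#' Specification for seeded synthetic fixtures
#'
#' Describes a synthetic protein: attention stacks with planted hub tokens
#' (columns whose softmax logits are boosted, so they receive extra incoming
#' attention), class-signal embeddings, and generation sizes. All generators
#' are pure functions of their spec: identical spec, identical output.
#'
#' @param n_tokens sequence length n.
#' @param n_layers,n_heads attention stack shape (defaults 4 x 4).
#' @param hub_indices 1-based positions of planted hub tokens.
#' @param hub_strength additive boost on hub key columns, in softmax logit
#'   units (default 3).
#' @param embedding_dim token embedding dimension d (default 32).
#' @param n_classes,proteins_per_class corpus shape (defaults 5 x 20).
#' @param n_hubs hubs planted per protein in corpus generation (default 3).
#' @param noise_sd embedding noise standard deviation (default 1).
#' @param signal_norm Euclidean norm of each class signal vector (default 5).
#' @param seed integer seed.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_tokens = 50L, n_layers = 4L, n_heads = 4L,
                         hub_indices = integer(0), hub_strength = 3,
                         embedding_dim = 32L, n_classes = 5L,
                         proteins_per_class = 20L, n_hubs = 3L,
                         noise_sd = 1, signal_norm = 5, seed = 1L) {
  stopifnot(n_tokens >= 1L, n_layers >= 1L, n_heads >= 1L,
            embedding_dim >= 1L, n_classes >= 1L, proteins_per_class >= 1L,
            noise_sd > 0, signal_norm >= 0, n_hubs >= 0L)
  hub_indices <- as.integer(hub_indices)
  if (length(hub_indices) &&
      (min(hub_indices) < 1L || max(hub_indices) > n_tokens))
    stop(sprintf("hub indices must lie in [1, %d]", n_tokens))
  structure(
    list(n_tokens = as.integer(n_tokens), n_layers = as.integer(n_layers),
         n_heads = as.integer(n_heads), hub_indices = hub_indices,
         hub_strength = hub_strength, embedding_dim = as.integer(embedding_dim),
         n_classes = as.integer(n_classes),
         proteins_per_class = as.integer(proteins_per_class),
         n_hubs = as.integer(n_hubs), noise_sd = noise_sd,
         signal_norm = signal_norm, seed = as.integer(seed)),
    class = "fixture_spec")
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

gen_one_stack <- function(spec, hub_indices) {
  n <- spec$n_tokens
  mats <- vector("list", spec$n_layers * spec$n_heads)
  for (i in seq_along(mats)) {
    logits <- matrix(stats::rnorm(n * n), n, n)
    if (length(hub_indices) && spec$hub_strength != 0)
      logits[, hub_indices] <- logits[, hub_indices] + spec$hub_strength
    mats[[i]] <- softmax_rows(logits)
  }
  attention_stack(mats, spec$n_layers, spec$n_heads, row_stochastic = TRUE)
}

#' Generate a planted-hub attention stack
#'
#' Per (layer, head) matrix: i.i.d. standard-normal logits, hub key columns
#' incremented by `hub_strength`, rows mapped through softmax so every row is
#' strictly positive and sums to one. The special mask is all-`FALSE`.
#' Reproducible under `spec$seed`.
#'
#' @param spec a [fixture_spec()]; `hub_indices` names the planted hubs.
#' @return an [attention_stack()].
#' @export
gen_attention_stack <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  gen_one_stack(spec, spec$hub_indices)
}

#' Generate a labeled corpus with planted class signal on hub positions
#'
#' Each class gets a fixed unit direction scaled to `signal_norm`. Each
#' protein receives i.i.d. Gaussian token embeddings (sd `noise_sd`); its
#' `n_hubs` hub rows additionally carry the class signal, and a planted-hub
#' attention stack concentrates attention on the same positions. Token-level
#' data are pooled immediately with the graph-PageRank pooler and the
#' baselines, so only per-protein embeddings are retained.
#'
#' @param spec a [fixture_spec()].
#' @param config a [pagerank_config()] used for the graph-PageRank pooling.
#' @return object of class `labeled_corpus`: list with `ids`, `labels`,
#'   `hub_positions` (list of 1-based hub indices per protein), `embeddings`
#'   (named list of protein x d matrices, one per pooling method: `parti`,
#'   `mean`, `max`, `sum`, `first_row`), and `class_signals` (class x d).
#' @export
gen_labeled_corpus <- function(spec, config = pagerank_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_tokens; d <- spec$embedding_dim
  n_prot <- spec$n_classes * spec$proteins_per_class
  signals <- matrix(stats::rnorm(spec$n_classes * d), spec$n_classes, d)
  signals <- signals / sqrt(rowSums(signals^2)) * spec$signal_norm
  methods <- c("parti", "mean", "max", "sum", "first_row")
  emb <- lapply(methods, function(m) matrix(NA_real_, n_prot, d))
  names(emb) <- methods
  ids <- character(n_prot); labels <- character(n_prot)
  hubs <- vector("list", n_prot)
  p <- 0L
  for (cl in seq_len(spec$n_classes)) {
    for (j in seq_len(spec$proteins_per_class)) {
      p <- p + 1L
      ids[p] <- sprintf("C%02d_P%03d", cl, j)
      labels[p] <- sprintf("class%02d", cl)
      hub <- sort(sample.int(n, spec$n_hubs))
      hubs[[p]] <- hub
      E <- matrix(stats::rnorm(n * d, sd = spec$noise_sd), n, d)
      E[hub, ] <- E[hub, , drop = FALSE] +
        matrix(signals[cl, ], length(hub), d, byrow = TRUE)
      stack <- gen_one_stack(spec, hub)
      te <- token_embeddings(E)
      emb$parti[p, ] <- pool_parti(stack, te, config)$embedding$vector
      emb$mean[p, ] <- baseline_pool(te, "mean")$vector
      emb$max[p, ]  <- baseline_pool(te, "max")$vector
      emb$sum[p, ]  <- baseline_pool(te, "sum")$vector
      emb$first_row[p, ] <- E[1L, ]
    }
  }
  for (m in methods) rownames(emb[[m]]) <- ids
  structure(list(ids = ids, labels = labels, hub_positions = hubs,
                 embeddings = emb, class_signals = signals, spec = spec),
            class = "labeled_corpus")
}

#' Extract a retrieval corpus for one pooling method
#'
#' @param corpus a [gen_labeled_corpus()] result.
#' @param method one of the pooling method names stored in the corpus.
#' @return a [retrieval_corpus()].
#' @export
as_retrieval_corpus <- function(corpus, method = "parti") {
  stopifnot(inherits(corpus, "labeled_corpus"))
  if (!method %in% names(corpus$embeddings))
    stop(sprintf("unknown pooling method '%s'", method))
  retrieval_corpus(corpus$ids, corpus$embeddings[[method]], corpus$labels)
}

#' Generate a database of random importance vectors
#'
#' Each vector is i.i.d. uniform(0, 1) then normalized to sum to one; used to
#' drive the empirical Jaccard null.
#'
#' @param n_proteins number of vectors.
#' @param length_ residue count of every vector.
#' @param seed integer seed.
#' @return list of `importance_vector`s.
#' @export
gen_importance_db <- function(n_proteins, length_, seed = 1L) {
  stopifnot(n_proteins >= 1L, length_ >= 1L)
  set.seed(seed)
  lapply(seq_len(n_proteins), function(i) {
    w <- stats::runif(length_)
    importance_vector(w / sum(w))
  })
}
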