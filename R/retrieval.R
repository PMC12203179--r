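#' Labeled embedding corpus for retrieval evaluation
#'
#' @param ids character vector of unique protein ids.
#' @param embeddings numeric matrix, one row per protein (same order as
#'   `ids`), no all-zero rows.
#' @param labels class labels (coerced to character), one per protein; every
#'   class must have at least two members.
#' @return object of class `retrieval_corpus`.
#' @export
retrieval_corpus <- function(ids, embeddings, labels) {
  ids <- as.character(ids)
  labels <- as.character(labels)
  if (anyDuplicated(ids)) stop("protein ids must be unique")
  if (!is.matrix(embeddings) || nrow(embeddings) != length(ids) ||
      length(labels) != length(ids))
    stop("ids, embedding rows, and labels must have matching lengths")
  norms <- sqrt(rowSums(embeddings^2))
  if (any(norms == 0)) stop("all-zero embeddings are not allowed")
  if (any(table(labels) < 2L))
    stop("every class must have at least 2 members")
  rownames(embeddings) <- ids
  structure(list(ids = ids, embeddings = embeddings, labels = labels,
                 dim = ncol(embeddings)),
            class = "retrieval_corpus")
}

cosine_to_query <- function(corpus, query_id) {
  qi <- match(query_id, corpus$ids)
  if (is.na(qi)) stop(sprintf("unknown protein id '%s'", query_id))
  E <- corpus$embeddings
  q <- E[qi, ]
  sims <- as.vector(E %*% q) / (sqrt(rowSums(E^2)) * sqrt(sum(q^2)))
  list(qi = qi, sims = sims)
}

#' Rank corpus members by cosine similarity to a query
#'
#' All members other than the query itself, sorted by decreasing cosine
#' similarity; exact ties are broken by ascending id so the order is
#' deterministic.
#'
#' @param corpus a [retrieval_corpus()].
#' @param query_id id of the query protein.
#' @return data frame with columns `id`, `similarity`, `label`, in rank order.
#' @export
rank_neighbors <- function(corpus, query_id) {
  cq <- cosine_to_query(corpus, query_id)
  keep <- seq_along(corpus$ids)[-cq$qi]
  ord <- keep[order(-cq$sims[keep], corpus$ids[keep])]
  data.frame(id = corpus$ids[ord], similarity = cq$sims[ord],
             label = corpus$labels[ord], stringsAsFactors = FALSE)
}

#' Precision at a fraction of the query's class size
#'
#' Retrieves the top `r = max(1, ceiling(fraction * class_size))` neighbors
#' of the query (self excluded) and returns the proportion that share the
#' query's class. The class size counts the query itself.
#'
#' @param corpus a [retrieval_corpus()].
#' @param query_id query protein id.
#' @param fraction fraction of class size to retrieve (default 0.10).
#' @return precision in \[0, 1\].
#' @export
precision_at_class_fraction <- function(corpus, query_id, fraction = 0.10) {
  qi <- match(query_id, corpus$ids)
  if (is.na(qi)) stop(sprintf("unknown protein id '%s'", query_id))
  cls <- corpus$labels[qi]
  m_c <- sum(corpus$labels == cls)
  if (m_c < 2L)
    stop(sprintf("precision undefined: class '%s' is a singleton", cls))
  r <- max(1L, as.integer(ceiling(fraction * m_c)))
  nb <- rank_neighbors(corpus, query_id)
  mean(nb$label[seq_len(r)] == cls)
}

#' Mean reciprocal rank of the first same-class neighbor
#'
#' @param corpus a [retrieval_corpus()].
#' @param query_ids queries to average over (default: all corpus members).
#' @return MRR in (0, 1].
#' @export
mean_reciprocal_rank <- function(corpus, query_ids = corpus$ids) {
  rr <- vapply(query_ids, function(qid) {
    qi <- match(qid, corpus$ids)
    if (is.na(qi)) stop(sprintf("unknown protein id '%s'", qid))
    cls <- corpus$labels[qi]
    if (sum(corpus$labels == cls) < 2L)
      stop(sprintf("MRR undefined: class '%s' is a singleton", cls))
    nb <- rank_neighbors(corpus, qid)
    1 / which(nb$label == cls)[1L]
  }, numeric(1L))
  mean(rr)
}

#' Class-balanced sampling rounds of retrieval metrics
#'
#' Each round samples `per_class` members from every class without
#' replacement, forms the sampled sub-corpus, and computes precision at the
#' class-size fraction and MRR averaged over all sampled queries within that
#' sub-corpus. Reports per-round values plus the mean and standard error
#' across rounds.
#'
#' @param corpus a [retrieval_corpus()].
#' @param per_class members sampled per class each round.
#' @param n_rounds number of rounds (default 50).
#' @param seed integer seed for reproducible sampling.
#' @param fraction retrieval-depth fraction (default 0.10).
#' @return list with `rounds` (data frame: round, precision, mrr) and
#'   `summary` (data frame: metric, mean, se).
#' @export
balanced_rounds <- function(corpus, per_class, n_rounds = 50L, seed = 1L,
                            fraction = 0.10) {
  classes <- split(seq_along(corpus$ids), corpus$labels)
  small <- names(classes)[vapply(classes, length, integer(1L)) < per_class]
  if (length(small))
    stop(sprintf("class '%s' has fewer than per_class = %d members",
                 small[1L], per_class))
  set.seed(seed)
  rows <- lapply(seq_len(n_rounds), function(rd) {
    idx <- sort(unlist(lapply(classes, function(ix)
      ix[sample.int(length(ix), per_class)]), use.names = FALSE))
    sub <- retrieval_corpus(corpus$ids[idx],
                            corpus$embeddings[idx, , drop = FALSE],
                            corpus$labels[idx])
    prec <- mean(vapply(sub$ids, precision_at_class_fraction,
                        numeric(1L), corpus = sub, fraction = fraction))
    data.frame(round = rd, precision = prec,
               mrr = mean_reciprocal_rank(sub))
  })
  rounds <- do.call(rbind, rows)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  list(rounds = rounds,
       summary = data.frame(
         metric = c("precision_at_fraction", "mrr"),
         mean = c(mean(rounds$precision), mean(rounds$mrr)),
         se = c(se(rounds$precision), se(rounds$mrr))))
}

#' Mann-Whitney U comparison of two per-round metric samples
#'
#' Two-sided test that the two pooling methods perform equally: exact
#' distribution when both samples have at most 8 values and no ties, normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param results_a,results_b numeric vectors of per-round metric values.
#' @return two-sided p-value.
#' @export
compare_methods <- function(results_a, results_b) {
  if (length(results_a) == 0L || length(results_b) == 0L)
    stop("both samples must be non-empty")
  no_ties <- !anyDuplicated(c(results_a, results_b))
  use_exact <- no_ties && length(results_a) <= 8L && length(results_b) <= 8L
  suppressWarnings(
    stats::wilcox.test(results_a, results_b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value)
}
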