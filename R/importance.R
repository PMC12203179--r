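#' Top-k-percentile residue set
#'
#' The `m = max(1, ceiling(k * n / 100))` residues with the largest
#' importance. Ties straddling the cutoff are broken toward the lower index,
#' so the set is deterministic. Positions are 1-based.
#'
#' @param alpha an `importance_vector` (or plain numeric vector).
#' @param k percentile cutoff in (0, 100].
#' @return object of class `top_set`: list with `indices` (sorted, 1-based),
#'   `n_residues`, `k`, `m`.
#' @export
top_percentile_set <- function(alpha, k) {
  w <- if (inherits(alpha, "importance_vector")) alpha$weights else alpha
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k > 100)
    stop("k must be a percent in (0, 100]")
  n <- length(w)
  m <- max(1L, as.integer(ceiling(k * n / 100)))
  ord <- order(-w, seq_len(n))
  structure(list(indices = sort(ord[seq_len(m)]), n_residues = n,
                 k = k, m = m),
            class = "top_set")
}

#' Jaccard index of two top sets
#'
#' @param a,b `top_set`s over the same residue count (or plain integer
#'   vectors; then the length check is skipped).
#' @return |a intersect b| / |a union b|, in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  if (inherits(a, "top_set") && inherits(b, "top_set") &&
      a$n_residues != b$n_residues)
    stop("top sets are over different residue counts")
  ia <- if (inherits(a, "top_set")) a$indices else a
  ib <- if (inherits(b, "top_set")) b$indices else b
  length(intersect(ia, ib)) / length(union(ia, ib))
}

#' Expected Jaccard index under random importance assignment
#'
#' Under the null that two length-n importance vectors are independent with
#' exchangeable ranks, their top-k sets are two independent uniform random
#' m-subsets of n (m = max(1, ceiling(k*n/100))). The overlap X is then
#' hypergeometric(n, m, m) and J = X / (2m - X), so the expectation is the
#' exact finite sum E[X / (2m - X)] over x = 0..m.
#'
#' @param n_prime residue count n.
#' @param k percentile cutoff in (0, 100].
#' @return the exact expected Jaccard index.
#' @export
expected_jaccard_random <- function(n_prime, k) {
  if (k <= 0 || k > 100) stop("k must be a percent in (0, 100]")
  n <- as.integer(n_prime)
  m <- max(1L, as.integer(ceiling(k * n / 100)))
  x <- 0:m
  sum(stats::dhyper(x, m, n - m, m) * x / (2 * m - x))
}

#' Empirical null of top-k Jaccard from same-length protein pairs
#'
#' Samples pairs of distinct proteins of the requested length from an
#' importance database and records the Jaccard index of their top-k sets —
#' the empirical background against which observed cross-model agreement is
#' judged.
#'
#' @param importance_db list of `importance_vector`s (or numeric vectors).
#' @param length_ residue count to condition on (exact match, unless
#'   `length_tol > 0` admits lengths within that absolute tolerance).
#' @param k percentile cutoff.
#' @param n_samples number of sampled pairs.
#' @param seed integer seed; the draw is reproducible.
#' @param length_tol nonnegative slack on the length match (default 0).
#' @return numeric vector of `n_samples` Jaccard values.
#' @export
empirical_null_jaccard <- function(importance_db, length_, k,
                                   n_samples = 1000L, seed = 1L,
                                   length_tol = 0L) {
  lens <- vapply(importance_db, function(v) {
    if (inherits(v, "importance_vector")) v$n_residues else length(v)
  }, integer(1L))
  pool <- which(abs(lens - length_) <= length_tol)
  if (length(pool) < 2L)
    stop(sprintf("need >= 2 proteins of length %d in the database (found %d)",
                 length_, length(pool)))
  tops <- lapply(importance_db[pool], top_percentile_set, k = k)
  set.seed(seed)
  vapply(seq_len(n_samples), function(i) {
    ij <- sample.int(length(pool), 2L)
    jaccard_index(tops[[ij[1L]]], tops[[ij[2L]]])
  }, numeric(1L))
}

#' Percentile rank of one residue's importance
#'
#' `100 * (number of residues with importance <= this one) / n`, with ties
#' counted at midrank, so the top residue of a tie-free vector scores 100 and
#' an all-equal vector gives every residue `100 * (n + 1) / (2n)`.
#'
#' @param alpha an `importance_vector` or numeric vector.
#' @param position 1-based residue position.
#' @return percentile rank in (0, 100].
#' @export
percentile_rank <- function(alpha, position) {
  w <- if (inherits(alpha, "importance_vector")) alpha$weights else alpha
  n <- length(w)
  if (position < 1L || position > n)
    stop(sprintf("position %d out of range [1, %d]", position, n))
  v <- w[position]
  n_less <- sum(w < v)
  n_eq <- sum(w == v)
  100 * (n_less + (n_eq + 1) / 2) / n
}

#' Percentile-rank profile of annotated residues with a uniformity test
#'
#' Pools the percentile ranks of all annotated residues across proteins and
#' tests them against the uniform null with a two-sided one-sample
#' Kolmogorov-Smirnov test. A heavy skew toward high percentiles indicates
#' that annotated (e.g. catalytic) residues receive systematically higher
#' importance than chance.
#'
#' @param alpha_by_protein named list of `importance_vector`s keyed by
#'   protein id.
#' @param annotations data frame with columns `protein_id`, `position`
#'   (1-based), and optionally `kind`.
#' @return list with `percentiles` (numeric vector), `ks_statistic`,
#'   `p_value`, `n_annotations`.
#' @export
annotation_percentile_profile <- function(alpha_by_protein, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L)
    stop("annotation set is empty")
  stopifnot(all(c("protein_id", "position") %in% names(annotations)))
  pct <- vapply(seq_len(nrow(annotations)), function(i) {
    id <- as.character(annotations$protein_id[i])
    if (is.null(alpha_by_protein[[id]]))
      stop(sprintf("unknown protein id '%s' in annotations", id))
    percentile_rank(alpha_by_protein[[id]], annotations$position[i])
  }, numeric(1L))
  ks <- suppressWarnings(
    stats::ks.test(pct, stats::punif, min = 0, max = 100))
  list(percentiles = pct, ks_statistic = unname(ks$statistic),
       p_value = ks$p.value, n_annotations = length(pct))
}

#' Interface-overlap classification at a percentile threshold
#'
#' Labels every residue by the 2x2 contrast between membership in a known
#' binding interface and membership in the top-k importance set:
#' TP (both), FN (interface only), FP (top set only), TN (neither). The
#' default threshold is the top 15% of predicted importance.
#'
#' @param alpha an `importance_vector`.
#' @param interface_positions 1-based residue positions of the interface.
#' @param threshold_k percentile threshold (default 15).
#' @return object of class `overlap_classification`: list with `labels`
#'   (character vector of length n), `counts` (named TP/FN/FP/TN),
#'   `threshold_k`, `top_set`.
#' @export
interface_overlap <- function(alpha, interface_positions, threshold_k = 15) {
  w <- if (inherits(alpha, "importance_vector")) alpha$weights else alpha
  n <- length(w)
  pos <- unique(as.integer(interface_positions))
  if (length(pos) && (min(pos) < 1L || max(pos) > n))
    stop(sprintf("interface positions must lie in [1, %d]", n))
  ts <- top_percentile_set(w, threshold_k)
  in_top <- seq_len(n) %in% ts$indices
  in_if <- seq_len(n) %in% pos
  labels <- ifelse(in_if & in_top, "TP",
            ifelse(in_if & !in_top, "FN",
            ifelse(!in_if & in_top, "FP", "TN")))
  counts <- c(TP = sum(labels == "TP"), FN = sum(labels == "FN"),
              FP = sum(labels == "FP"), TN = sum(labels == "TN"))
  structure(list(labels = labels, counts = counts,
                 threshold_k = threshold_k, top_set = ts),
            class = "overlap_classification")
}
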