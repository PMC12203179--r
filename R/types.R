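#' Attention stack for one protein
#'
#' Container for the per-(layer, head) attention matrices an encoder protein
#' language model emits for a single sequence, together with the mask of
#' special (non-residue) tokens such as the beginning-of-sequence/CLS and
#' end-of-sequence/SEP positions.
#'
#' @param matrices list of n x n nonnegative numeric matrices, ordered
#'   layer-major (all heads of layer 1, then layer 2, ...).
#' @param n_layers,n_heads number of layers L and heads per layer H;
#'   `length(matrices)` must equal `L * H`.
#' @param special_mask logical vector of length n; `TRUE` marks non-residue
#'   tokens. Default: all residues.
#' @param row_stochastic if `TRUE`, assert that every row of every matrix
#'   sums to 1 within 1e-4 (as softmax attention must).
#'
#' @return an object of class `attention_stack`.
#' @export
attention_stack <- function(matrices, n_layers, n_heads,
                            special_mask = NULL, row_stochastic = FALSE) {
  if (!is.list(matrices) || length(matrices) == 0L)
    stop("attention stack must contain at least one matrix (L*H >= 1)")
  if (length(matrices) != n_layers * n_heads)
    stop("length(matrices) must equal n_layers * n_heads")
  n <- nrow(matrices[[1L]])
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("attention matrices must be numeric matrices")
    if (nrow(m) != n || ncol(m) != n)
      stop(sprintf("matrix %d is %dx%d, expected %dx%d",
                   i, nrow(m), ncol(m), n, n))
    if (anyNA(m) || any(m < 0))
      stop(sprintf("matrix %d has negative or missing entries", i))
    if (row_stochastic) {
      rs <- rowSums(m)
      if (any(abs(rs - 1) > 1e-4))
        stop(sprintf("matrix %d is not row-stochastic (max |rowsum-1| = %.3g)",
                     i, max(abs(rs - 1))))
    }
  }
  if (is.null(special_mask)) special_mask <- rep(FALSE, n)
  if (!is.logical(special_mask) || length(special_mask) != n)
    stop("special_mask must be a logical vector of length n_tokens")
  structure(
    list(matrices = matrices, n_layers = n_layers, n_heads = n_heads,
         n_tokens = n, special_mask = special_mask),
    class = "attention_stack")
}

#' Token embedding matrix for one protein
#'
#' @param values n x d numeric matrix of per-token embeddings (one row per
#'   token, including special tokens as emitted by the model).
#' @param special_mask logical length-n vector marking non-residue tokens;
#'   must equal the paired [attention_stack()]'s mask.
#'
#' @return an object of class `token_embeddings`.
#' @export
token_embeddings <- function(values, special_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("token embedding matrix must have n >= 1 rows and d >= 1 columns")
  if (any(!is.finite(values)))
    stop("token embeddings must be finite")
  n <- nrow(values)
  if (is.null(special_mask)) special_mask <- rep(FALSE, n)
  if (!is.logical(special_mask) || length(special_mask) != n)
    stop("special_mask must be a logical vector of length n_tokens")
  structure(
    list(values = values, n_tokens = n, dim = ncol(values),
         special_mask = special_mask),
    class = "token_embeddings")
}

#' @export
print.attention_stack <- function(x, ...) {
  cat(sprintf("attention_stack: %d tokens (%d special), %d layers x %d heads\n",
              x$n_tokens, sum(x$special_mask), x$n_layers, x$n_heads))
  invisible(x)
}

#' @export
print.token_embeddings <- function(x, ...) {
  cat(sprintf("token_embeddings: %d tokens (%d special), dim %d\n",
              x$n_tokens, sum(x$special_mask), x$dim))
  invisible(x)
}

#' PageRank configuration
#'
#' Defaults follow the standard damped random-surfer setting used by the
#' pooling algorithm: damping 0.85, at most 100 iterations, per-node
#' tolerance 1e-6 (iteration stops when the L1 change is below
#' `n * tolerance`).
#'
#' @param damping teleport-complement probability in \[0, 1\].
#' @param max_iterations positive integer iteration cap.
#' @param tolerance positive per-node convergence tolerance.
#' @param on_nonconvergence `"fail"` to raise an error when the cap is hit
#'   without convergence, `"return-last"` to warn and return the last iterate.
#'
#' @return an object of class `pagerank_config`.
#' @export
pagerank_config <- function(damping = 0.85, max_iterations = 100L,
                            tolerance = 1e-6,
                            on_nonconvergence = c("fail", "return-last")) {
  stopifnot(is.numeric(damping), length(damping) == 1L,
            damping >= 0, damping <= 1,
            max_iterations >= 1L, tolerance > 0)
  structure(
    list(damping = damping,
         max_iterations = as.integer(max_iterations),
         tolerance = tolerance,
         on_nonconvergence = match.arg(on_nonconvergence)),
    class = "pagerank_config")
}
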