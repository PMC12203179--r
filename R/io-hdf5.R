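#' Tensor-exchange HDF5 layout
#'
#' One group per protein id holding datasets `embeddings` (n x d),
#' `special_mask` (length n, 0/1), and either `attention`
#' (n x n x H x L) or `attention_pooled` (n x n), with group attributes
#' `sequence`, `model`, `prepooled`, `n_layers`, `n_heads`. Floats are
#' stored as 32-bit on disk; all computation is double precision.
#'
#' @name tensor_exchange
NULL

h5_write_f32 <- function(file, name, x) {
  rhdf5::h5createDataset(file, name, dims = dim(x),
                         H5type = "H5T_IEEE_F32LE")
  rhdf5::h5write(x, file, name)
}

#' Write one protein record to a tensor-exchange file
#'
#' @param path HDF5 file path (created if absent; existing groups for other
#'   ids are kept).
#' @param id protein id (group name).
#' @param emb a [token_embeddings()].
#' @param stack an [attention_stack()], or `NULL` when `pooled` is given.
#' @param pooled a `pooled_attention` (or n x n matrix) to store pre-pooled;
#'   exactly one of `stack`/`pooled` must be non-`NULL`.
#' @param sequence amino-acid sequence string (may be empty).
#' @param model model name string.
#' @return `path`, invisibly.
#' @export
write_record <- function(path, id, emb, stack = NULL, pooled = NULL,
                         sequence = "", model = "synthetic") {
  stopifnot(inherits(emb, "token_embeddings"))
  if (is.null(stack) == is.null(pooled))
    stop("provide exactly one of 'stack' or 'pooled'")
  if (!file.exists(path)) rhdf5::h5createFile(path)
  grp <- paste0("/", id)
  rhdf5::h5createGroup(path, grp)
  h5_write_f32(path, paste0(grp, "/embeddings"), emb$values)
  rhdf5::h5write(as.integer(emb$special_mask), path,
                 paste0(grp, "/special_mask"))
  if (!is.null(stack)) {
    stopifnot(inherits(stack, "attention_stack"))
    if (!identical(stack$special_mask, emb$special_mask))
      stop("special_mask mismatch between stack and embeddings")
    n <- stack$n_tokens
    arr <- array(unlist(stack$matrices, use.names = FALSE),
                 dim = c(n, n, stack$n_heads, stack$n_layers))
    h5_write_f32(path, paste0(grp, "/attention"), arr)
    meta <- c(prepooled = 0L, n_layers = stack$n_layers,
              n_heads = stack$n_heads)
  } else {
    W <- if (inherits(pooled, "pooled_attention")) pooled$matrix else pooled
    if (nrow(W) != sum(!emb$special_mask))
      stop("pre-pooled attention must cover the residue tokens only")
    h5_write_f32(path, paste0(grp, "/attention_pooled"), W)
    meta <- c(prepooled = 1L, n_layers = NA_integer_, n_heads = NA_integer_)
  }
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  gid <- rhdf5::H5Gopen(fid, grp)
  on.exit(rhdf5::H5Gclose(gid), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(sequence, gid, "sequence")
  rhdf5::h5writeAttribute(model, gid, "model")
  rhdf5::h5writeAttribute(meta[["prepooled"]], gid, "prepooled")
  if (!is.na(meta[["n_layers"]])) {
    rhdf5::h5writeAttribute(meta[["n_layers"]], gid, "n_layers")
    rhdf5::h5writeAttribute(meta[["n_heads"]], gid, "n_heads")
  }
  invisible(path)
}

#' List protein ids stored in a tensor-exchange file
#' @param path HDF5 file path.
#' @return character vector of ids.
#' @export
list_record_ids <- function(path) {
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  ls$name[ls$otype == "H5I_GROUP"]
}

#' Read one protein record from a tensor-exchange file
#'
#' @param path HDF5 file path.
#' @param id protein id; must name a group in the file.
#' @return list with `id`, `emb` ([token_embeddings()]), `prepooled` flag,
#'   and either `stack` ([attention_stack()]) or `pooled`
#'   (`pooled_attention`), plus `sequence` and `model`.
#' @export
read_record <- function(path, id) {
  if (!id %in% list_record_ids(path))
    stop(sprintf("no record '%s' in %s", id, path))
  grp <- paste0("/", id)
  at <- rhdf5::h5readAttributes(path, grp)
  E <- rhdf5::h5read(path, paste0(grp, "/embeddings"))
  mask <- as.logical(rhdf5::h5read(path, paste0(grp, "/special_mask")))
  if (length(mask) != nrow(E))
    stop("format error in field 'special_mask': length does not match embedding rows")
  emb <- token_embeddings(matrix(as.numeric(E), nrow(E), ncol(E)),
                          special_mask = mask)
  prepooled <- isTRUE(as.integer(at$prepooled) == 1L)
  out <- list(id = id, emb = emb, prepooled = prepooled,
              sequence = as.character(at$sequence),
              model = as.character(at$model))
  if (prepooled) {
    W <- rhdf5::h5read(path, paste0(grp, "/attention_pooled"))
    if (length(dim(W)) != 2L || nrow(W) != ncol(W))
      stop("format error in field 'attention_pooled': expected a square matrix")
    if (nrow(W) != sum(!mask))
      stop("format error in field 'attention_pooled': size does not match residue count")
    out$pooled <- structure(
      list(matrix = matrix(as.numeric(W), nrow(W), ncol(W)),
           n_residues = nrow(W)),
      class = "pooled_attention")
  } else {
    A <- rhdf5::h5read(path, paste0(grp, "/attention"))
    if (length(dim(A)) != 4L || dim(A)[1L] != nrow(E) ||
        dim(A)[2L] != nrow(E))
      stop("format error in field 'attention': shape contradicts prepooled flag")
    L <- as.integer(at$n_layers); H <- as.integer(at$n_heads)
    n <- dim(A)[1L]
    mats <- vector("list", L * H)
    k <- 0L
    for (l in seq_len(L)) for (h in seq_len(H)) {
      k <- k + 1L
      mats[[k]] <- matrix(as.numeric(A[, , h, l]), n, n)
    }
    out$stack <- attention_stack(mats, L, H, special_mask = mask)
  }
  out
}

#' Streaming pixelwise max pooling
#'
#' Consumes attention matrices one at a time from a provider function and
#' keeps a running elementwise maximum, so at most two n x n matrices are
#' resident at once — full L x H x n x n stacks for long sequences need never
#' be materialized. The result equals [max_pool_attention()] on the full
#' stack exactly.
#'
#' @param provider a function that returns the next n x n matrix, or `NULL`
#'   when exhausted (see [attention_provider()]).
#' @return a `pooled_attention`.
#' @export
streaming_max_pool <- function(provider) {
  pooled <- provider()
  if (is.null(pooled)) stop("provider yielded no matrices")
  repeat {
    m <- provider()
    if (is.null(m)) break
    if (!identical(dim(m), dim(pooled)))
      stop(sprintf("shape change mid-stream: %dx%d after %dx%d",
                   nrow(m), ncol(m), nrow(pooled), ncol(pooled)))
    pooled <- pmax(pooled, m)
  }
  structure(list(matrix = pooled, n_residues = nrow(pooled)),
            class = "pooled_attention")
}

#' Matrix provider over an in-memory attention stack
#'
#' Implements the provider contract for [streaming_max_pool()]: each call
#' yields the next (layer, head) matrix, then `NULL`.
#'
#' @param stack an [attention_stack()].
#' @return a zero-argument function.
#' @export
attention_provider <- function(stack) {
  stopifnot(inherits(stack, "attention_stack"))
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > length(stack$matrices)) NULL else stack$matrices[[i]]
  }
}

#' Matrix provider streaming from a tensor-exchange file
#'
#' Reads one (layer, head) attention slice per call from an HDF5 record, so
#' the full stack never resides in memory.
#'
#' @param path HDF5 file path.
#' @param id protein id of a non-prepooled record.
#' @return a zero-argument provider function.
#' @export
hdf5_attention_provider <- function(path, id) {
  at <- rhdf5::h5readAttributes(path, paste0("/", id))
  if (isTRUE(as.integer(at$prepooled) == 1L))
    stop(sprintf("record '%s' is pre-pooled; nothing to stream", id))
  L <- as.integer(at$n_layers); H <- as.integer(at$n_heads)
  mask <- as.logical(rhdf5::h5read(path, paste0("/", id, "/special_mask")))
  n <- length(mask)
  k <- 0L
  function() {
    k <<- k + 1L
    if (k > L * H) return(NULL)
    l <- (k - 1L) %/% H + 1L
    h <- (k - 1L) %% H + 1L
    sl <- rhdf5::h5read(path, paste0("/", id, "/attention"),
                        index = list(NULL, NULL, h, l))
    matrix(as.numeric(sl), n, n)
  }
}
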