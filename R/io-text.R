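AA_ALPHABET <- c(LETTERS[!LETTERS %in% c("J", "O")], "X", "B", "Z", "U")
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a FASTA file of amino-acid sequences
#'
#' Standard multi-record FASTA; the id is the description line up to the
#' first whitespace. Lowercase letters are accepted and uppercased. Allowed
#' letters are the 20 standard amino acids plus X, B, Z, U (extendable via
#' `extra_letters`); anything else is reported with its record and offset.
#'
#' @param path FASTA file.
#' @param extra_letters additional single characters to accept.
#' @return named character vector of sequences (names are ids).
#' @export
read_fasta <- function(path, extra_letters = character(0)) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1L), 1L)
  allowed <- c(AA_STANDARD, "X", "B", "Z", "U", toupper(extra_letters))
  out <- toupper(as.character(seqs))
  for (i in seq_along(out)) {
    ch <- strsplit(out[i], "")[[1]]
    bad <- which(!ch %in% allowed)
    if (length(bad))
      stop(sprintf("illegal character '%s' in record '%s' at position %d",
                   ch[bad[1L]], ids[i], bad[1L]))
  }
  stats::setNames(out, ids)
}

#' Write per-residue importance to TSV
#'
#' Columns: protein_id, position (1-based), residue, importance, percentile
#' (midrank percentile of the importance within the protein). A header
#' comment states the coordinate convention.
#'
#' @param path output TSV path.
#' @param records list of lists with fields `id`, `alpha` (an
#'   `importance_vector` or numeric vector) and optional `sequence`.
#' @return `path`, invisibly.
#' @export
write_importance_tsv <- function(path, records) {
  rows <- lapply(records, function(r) {
    w <- if (inherits(r$alpha, "importance_vector")) r$alpha$weights else r$alpha
    n <- length(w)
    res <- if (!is.null(r$sequence) && nzchar(r$sequence))
      strsplit(r$sequence, "")[[1]][seq_len(n)] else rep(NA_character_, n)
    pct <- vapply(seq_len(n), function(i) percentile_rank(w, i), numeric(1L))
    data.frame(protein_id = r$id, position = seq_len(n), residue = res,
               importance = w, percentile = pct, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-residue importance; positions are 1-based", con)
  utils::write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an importance TSV written by [write_importance_tsv()]
#' @param path TSV path.
#' @return data frame with the five columns.
#' @export
read_importance_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "importance")
  if (!all(need %in% names(df)))
    stop(sprintf("importance TSV %s lacks required columns", path))
  df
}

importance_tsv_to_db <- function(df) {
  lapply(split(df, df$protein_id), function(g) {
    g <- g[order(g$position), ]
    normalize_importance(g$importance)
  })
}

#' Write sequence embeddings to TSV (one row per protein)
#' @param path output path.
#' @param ids protein ids.
#' @param embeddings numeric matrix, one row per id.
#' @return `path`, invisibly.
#' @export
write_embeddings_tsv <- function(path, ids, embeddings) {
  stopifnot(length(ids) == nrow(embeddings))
  df <- data.frame(protein_id = ids,
                   signif(embeddings, 12),
                   stringsAsFactors = FALSE)
  names(df) <- c("protein_id", sprintf("e%d", seq_len(ncol(embeddings))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sequence embeddings; one protein per row", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sequence-embedding TSV
#' @param path TSV path.
#' @return list with `ids` and `embeddings` matrix.
#' @export
read_embeddings_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  list(ids = df$protein_id,
       embeddings = as.matrix(df[, -1L, drop = FALSE]))
}

#' Read a labels TSV (columns protein_id, label)
#' @param path TSV path.
#' @return data frame.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("protein_id", "label") %in% names(df)))
    stop(sprintf("labels TSV %s must have columns protein_id, label", path))
  df
}

#' Read an annotation TSV (columns protein_id, position, kind)
#' @param path TSV path.
#' @return data frame.
#' @export
read_annotations_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("protein_id", "position") %in% names(df)))
    stop(sprintf("annotation TSV %s must have columns protein_id, position", path))
  df
}

#' Map per-residue importance onto a PDB structure's B-factor column
#'
#' Sets the B-factor of every atom whose residue number matches a position in
#' the importance table to `100 * importance` (clamped to the fixed-width PDB
#' field). Importance is defined over the full sequence; structures often
#' resolve only a segment, so unmatched structure residues are left untouched
#' and counted.
#'
#' @param structure_path input PDB file.
#' @param importance numeric vector over the full sequence (1-based residue
#'   numbering), or a data frame with `position` and `importance` columns.
#' @param out_path output PDB path.
#' @param chain optional chain identifier to restrict the mapping.
#' @return list with `n_matched` and `n_unmatched` residue counts, invisibly
#'   annotated file written to `out_path`.
#' @export
write_bfactor_pdb <- function(structure_path, importance, out_path,
                              chain = NULL) {
  if (is.data.frame(importance)) {
    imp <- rep(NA_real_, max(importance$position))
    imp[importance$position] <- importance$importance
  } else imp <- as.numeric(importance)
  pdb <- bio3d::read.pdb(structure_path)
  atoms <- pdb$atom
  sel <- rep(TRUE, nrow(atoms))
  if (!is.null(chain)) sel <- atoms$chain %in% chain
  resno <- atoms$resno
  matched <- sel & resno >= 1L & resno <= length(imp) &
    !is.na(imp[pmax(pmin(resno, length(imp)), 1L)])
  if (!any(matched))
    stop("no structure residues matched the importance table")
  b <- pmin(pmax(100 * imp[resno[matched]], 0), 999.99)
  pdb$atom$b[matched] <- round(b, 2)
  bio3d::write.pdb(pdb, file = out_path)
  res_ids <- paste(atoms$chain, resno)
  list(n_matched = length(unique(res_ids[matched & atoms$type == "ATOM"])),
       n_unmatched = length(unique(res_ids[sel & !matched &
                                             atoms$type == "ATOM"])))
}
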