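# Canonical amino-acid alphabet, the ordering that fixes trigram indices.
AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"
AMBIGUOUS_AA <- c("B", "O", "J", "U", "X", "Z")
SEQ_MAX_LENGTH <- 1002L
SEQ_POSITIONS <- 1000L

.aa_chars <- strsplit(AA_ALPHABET, "")[[1]]

#' Validate a protein sequence
#'
#' A sequence is usable iff its length is in `[3, 1002]` and it contains only
#' the 20 canonical residues (ACDEFGHIKLMNPQRSTVWY). Ambiguous or
#' non-standard codes (B, O, J, U, X, Z and anything else) are rejected.
#' Lowercase input is uppercased first.
#'
#' @param seq a single amino-acid string.
#' @param id optional accession recorded on the result.
#' @return On success, a `protein_record`: `list(id, sequence)`. On failure a
#'   `sequence_rejection`: `list(id, reason, detail, position)` where
#'   `reason` is one of `"too long"`, `"too short"`, `"bad residue"`.
#' @export
validate_sequence <- function(seq, id = NA_character_) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n > SEQ_MAX_LENGTH)
    return(structure(list(id = id, reason = "too long",
                          detail = sprintf("length %d > %d", n, SEQ_MAX_LENGTH),
                          position = NA_integer_), class = "sequence_rejection"))
  if (n < 3L)
    return(structure(list(id = id, reason = "too short",
                          detail = sprintf("length %d < 3", n),
                          position = NA_integer_), class = "sequence_rejection"))
  codes <- utf8ToInt(seq)
  ok <- codes %in% utf8ToInt(AA_ALPHABET)
  if (!all(ok)) {
    pos <- which(!ok)[1]
    ch <- substr(seq, pos, pos)
    return(structure(list(id = id, reason = "bad residue",
                          detail = sprintf("residue '%s' at position %d", ch, pos),
                          position = pos), class = "sequence_rejection"))
  }
  structure(list(id = id, sequence = seq), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", nchar(x$sequence), " aa)\n", sep = "")
  invisible(x)
}

#' Validate a set of sequences, keeping an attrition report
#'
#' @param seqs named character vector of sequences.
#' @return list with `records` (named character vector of accepted
#'   sequences) and `dropped` (data.frame id / reason / detail).
#' @export
validate_proteins <- function(seqs) {
  res <- lapply(names(seqs), function(id) validate_sequence(seqs[[id]], id))
  ok <- vapply(res, inherits, TRUE, "protein_record")
  kept <- vapply(res[ok], `[[`, "", "sequence")
  names(kept) <- vapply(res[ok], `[[`, "", "id")
  dropped <- data.frame(
    id = vapply(res[!ok], `[[`, "", "id"),
    reason = vapply(res[!ok], `[[`, "", "reason"),
    detail = vapply(res[!ok], `[[`, "", "detail"),
    stringsAsFactors = FALSE)
  list(records = kept, dropped = dropped)
}

#' The amino-acid trigram vocabulary
#'
#' All 20^3 = 8000 trigrams over the canonical alphabet, enumerated in
#' lexicographic order and numbered 1..8000; index 0 is reserved for padding.
#'
#' @return A `trigram_vocab`: list with `trigrams` (character vector, rank
#'   order) and `index` (named integer vector trigram -> 1-based index).
#' @export
build_vocabulary <- function() {
  g <- expand.grid(c3 = .aa_chars, c2 = .aa_chars, c1 = .aa_chars,
                   stringsAsFactors = FALSE)
  tri <- paste0(g$c1, g$c2, g$c3)
  idx <- seq_along(tri); names(idx) <- tri
  structure(list(trigrams = tri, index = idx), class = "trigram_vocab")
}

#' @export
print.trigram_vocab <- function(x, ...) {
  cat("<trigram_vocab> ", length(x$trigrams), " trigrams (",
      x$trigrams[1], " = 1 ... ", x$trigrams[length(x$trigrams)], " = ",
      length(x$trigrams), ")\n", sep = "")
  invisible(x)
}

# residue -> 0..19 rank, arithmetic fast path shared by the encoders
.aa_rank <- local({
  r <- rep(NA_integer_, 127L)
  r[utf8ToInt(AA_ALPHABET)] <- 0:19
  r
})

#' Encode a sequence as a fixed-length trigram index vector
#'
#' Overlapping trigrams at positions `i..i+2` are mapped to their 1-based
#' vocabulary index; the vector is post-padded with zeros to 1000 entries, so
#' a maximum-length (1002 aa) sequence fills it exactly.
#'
#' @param seq a validated sequence string (or a `protein_record`).
#' @param positions output length (1000).
#' @return Integer vector of length `positions`; the nonzero prefix has
#'   length `nchar(seq) - 2`.
#' @export
encode_sequence <- function(seq, positions = SEQ_POSITIONS) {
  if (inherits(seq, "protein_record")) seq <- seq$sequence
  n <- nchar(seq)
  stopifnot(n >= 3L, n <= positions + 2L)
  r <- .aa_rank[utf8ToInt(seq)]
  if (anyNA(r)) stop("sequence contains non-canonical residues; validate first")
  k <- n - 2L
  idx <- 400L * r[seq_len(k)] + 20L * r[seq_len(k) + 1L] + r[seq_len(k) + 2L] + 1L
  c(idx, integer(positions - k))
}

#' Encode many sequences into an index matrix
#'
#' @param seqs named character vector of validated sequences.
#' @inheritParams encode_sequence
#' @return Integer matrix, one row per sequence (rownames = ids), 1000
#'   columns.
#' @export
encode_sequences <- function(seqs, positions = SEQ_POSITIONS) {
  m <- t(vapply(seqs, encode_sequence, integer(positions), positions = positions))
  rownames(m) <- names(seqs)
  m
}

#' Reconstruct a sequence from its trigram index vector
#'
#' Inverse of [encode_sequence()]: consecutive trigrams overlap by two
#' residues, so the sequence is the first trigram followed by the last
#' residue of each subsequent trigram.
#'
#' @param idx integer index vector (padded with zeros).
#' @param vocab a `trigram_vocab`.
#' @return The decoded amino-acid string.
#' @export
decode_sequence <- function(idx, vocab = build_vocabulary()) {
  idx <- idx[idx > 0L]
  if (!length(idx)) return("")
  tri <- vocab$trigrams[idx]
  paste0(tri[1], paste(substr(tri[-1], 3L, 3L), collapse = ""))
}

#' Binary label vector for a protein over a selected term set
#'
#' @param terms the protein's (propagated) annotation terms.
#' @param termset a `term_set`.
#' @return Integer 0/1 vector of length `length(termset$terms)`, position
#'   `termset$index[t] + 1` set to 1 iff `t` is annotated.
#' @export
encode_labels <- function(terms, termset) {
  v <- integer(length(termset$terms))
  hit <- intersect(terms, termset$terms)
  v[termset$index[hit] + 1L] <- 1L
  v
}

#' Read a (possibly wrapped) multi-record FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 60L)
  invisible(path)
}
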