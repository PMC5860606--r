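#' Load a protein network-embedding table
#'
#' Reads a headerless TSV whose rows are `id<TAB>v1<TAB>...<TAB>vD` with a
#' constant dimension D. Proteins absent from the table later resolve to the
#' zero vector (the fallback used for proteins without a network
#' representation), so lookups never fail.
#'
#' @param path TSV file (may be empty).
#' @param dim embedding dimension assumed when the file is empty (default
#'   256, the knowledge-graph embedding size).
#' @return An `embedding_table`: list with `vectors` (numeric matrix, one row
#'   per id) and `dim`.
#' @export
load_embeddings <- function(path, dim = 256L) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (is.null(nf) || !length(nf)) {
    m <- matrix(numeric(0), nrow = 0, ncol = dim)
    return(structure(list(vectors = m, dim = as.integer(dim)),
                     class = "embedding_table"))
  }
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged embedding table: line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric embedding values in ", path)
  if (anyDuplicated(ids)) {
    warning("duplicate embedding id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            "; last occurrence wins")
    keep <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[keep]; m <- m[keep, , drop = FALSE]
  }
  rownames(m) <- ids
  structure(list(vectors = m, dim = ncol(m)), class = "embedding_table")
}

#' Build an embedding table from a matrix
#'
#' @param m numeric matrix with protein ids as rownames.
#' @return An `embedding_table`.
#' @export
embedding_table <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  structure(list(vectors = m, dim = ncol(m)), class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", nrow(x$vectors), " proteins x ", x$dim,
      " dimensions\n", sep = "")
  invisible(x)
}

#' Look up embedding vectors, zero-filling missing proteins
#'
#' @param table an `embedding_table`.
#' @param ids protein identifiers.
#' @return Numeric matrix `length(ids) x dim`; rows of zeros for ids not in
#'   the table.
#' @export
embedding_vectors <- function(table, ids) {
  out <- matrix(0, nrow = length(ids), ncol = table$dim,
                dimnames = list(ids, NULL))
  hit <- ids %in% rownames(table$vectors)
  if (any(hit)) out[hit, ] <- table$vectors[ids[hit], , drop = FALSE]
  out
}

#' Write an embedding table as TSV
#'
#' @param table an `embedding_table` (or matrix with rownames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  m <- if (inherits(table, "embedding_table")) table$vectors else table
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Transfer a network embedding to a novel protein via best sequence hit
#'
#' A query protein absent from the interaction network inherits the embedding
#' of its highest-scoring alignment hit among the reference proteins (the
#' BLAST-mediated transfer used at prediction time for unseen proteins). If
#' no reference aligns above the backend's reporting threshold, the zero
#' vector is returned. Tied best scores are resolved toward the
#' lexicographically smallest reference id.
#'
#' @param query a `protein_record` (or sequence string).
#' @param table an `embedding_table`.
#' @param reference named character vector of reference sequences.
#' @param backend an alignment backend, see [sw_backend()] / [blast_backend()].
#' @return Numeric vector of length `table$dim`.
#' @export
transfer_embedding <- function(query, table, reference, backend = sw_backend()) {
  if (!length(reference)) stop("empty reference set")
  hits <- align_scores(backend, query, reference)
  if (!nrow(hits)) return(numeric(table$dim))
  best <- hits[order(-hits$score, hits$id), , drop = FALSE][1, ]
  as.numeric(embedding_vectors(table, best$id))
}
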