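#' Built-in Smith-Waterman alignment backend
#'
#' Local alignment with BLOSUM62 scoring and affine gaps (open 11, extend 1,
#' the standard protein defaults). Alignments scoring below `min_score` are
#' not reported, which plays the role of BLAST's significance cutoff; without
#' it, any two random proteins share some tiny perfect-identity local match.
#'
#' @param min_score minimum raw alignment score for a hit to be reported.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param matrix substitution matrix name.
#' @return A backend object usable by [align_scores()].
#' @export
sw_backend <- function(min_score = 40, gap_open = 11, gap_extend = 1,
                       matrix = "BLOSUM62") {
  structure(list(min_score = min_score, gap_open = gap_open,
                 gap_extend = gap_extend, matrix = matrix),
            class = c("sw_backend", "alignment_backend"))
}

#' BLAST command-line alignment backend
#'
#' Shells out to `makeblastdb`/`blastp` (BLAST+) with tabular output. Only
#' hits with e-value at or below the cutoff are reported; the raw score used
#' for ranking is the bit score.
#'
#' @param evalue e-value reporting threshold (default 1e-3).
#' @return A backend object usable by [align_scores()].
#' @export
blast_backend <- function(evalue = 1e-3) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "")
    stop("blastp/makeblastdb not found on PATH")
  structure(list(evalue = evalue),
            class = c("blast_backend", "alignment_backend"))
}

#' Align a query against reference sequences
#'
#' @param backend an alignment backend.
#' @param query a `protein_record` or sequence string.
#' @param refs named character vector of reference sequences.
#' @return data.frame with columns `id`, `score`, `pident` (percent identical
#'   positions over the alignment length), one row per reference passing the
#'   backend's reporting threshold.
#' @export
align_scores <- function(backend, query, refs) UseMethod("align_scores")

#' @export
align_scores.sw_backend <- function(backend, query, refs) {
  q <- if (inherits(query, "protein_record")) query$sequence else query
  if (!nzchar(q)) stop("empty query sequence")
  if (any(!nzchar(refs))) stop("empty reference sequence")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(refs),
    subject = Biostrings::AAString(q),
    type = "local", substitutionMatrix = backend$matrix,
    gapOpening = backend$gap_open, gapExtension = backend$gap_extend)
  sc <- Biostrings::score(pa)
  pid <- Biostrings::pid(pa, type = "PID1")
  keep <- sc >= backend$min_score
  data.frame(id = names(refs)[keep], score = sc[keep], pident = pid[keep],
             stringsAsFactors = FALSE)
}

#' @export
align_scores.blast_backend <- function(backend, query, refs) {
  q <- if (inherits(query, "protein_record")) query$sequence else query
  if (!nzchar(q)) stop("empty query sequence")
  td <- tempfile("blastdb"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  dbf <- file.path(td, "db.fasta"); qf <- file.path(td, "q.fasta")
  write_fasta(refs, dbf)
  write_fasta(c(query = q), qf)
  system2("makeblastdb", c("-in", dbf, "-dbtype", "prot"),
          stdout = FALSE, stderr = FALSE)
  out <- system2("blastp", c("-query", qf, "-db", dbf,
                             "-outfmt", shQuote("6 sseqid bitscore pident"),
                             "-evalue", format(backend$evalue, scientific = TRUE),
                             "-max_target_seqs", length(refs)),
                 stdout = TRUE, stderr = FALSE)
  if (!length(out)) return(data.frame(id = character(0), score = numeric(0),
                                      pident = numeric(0)))
  f <- do.call(rbind, strsplit(out, "\t", fixed = TRUE))
  df <- data.frame(id = f[, 1], score = as.numeric(f[, 2]),
                   pident = as.numeric(f[, 3]), stringsAsFactors = FALSE)
  # keep the best HSP per subject
  df <- df[order(-df$score), , drop = FALSE]
  df[!duplicated(df$id), , drop = FALSE]
}

#' Percent sequence identity between two proteins
#'
#' Identical positions over the alignment length of the best local alignment
#' (the BLAST `pident` convention), taken as the maximum over both alignment
#' directions. If neither direction yields an alignment above the backend's
#' reporting threshold, the pair is considered unrelated and 0 is returned.
#'
#' @param a,b `protein_record`s or sequence strings.
#' @param backend an alignment backend.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, backend = sw_backend()) {
  sa <- if (inherits(a, "protein_record")) a$sequence else a
  sb <- if (inherits(b, "protein_record")) b$sequence else b
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence")
  h1 <- align_scores(backend, sa, c(x = sb))
  h2 <- align_scores(backend, sb, c(x = sa))
  max(0, h1$pident, h2$pident)
}
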