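#' Homology-reduced train/test split by pairwise sequence identity
#'
#' Builds a graph over the proteins with an edge wherever pairwise identity
#' reaches the threshold, then assigns whole connected components to the
#' training side (largest first) until the requested training fraction is
#' reached; the remaining components form the test side. By construction no
#' test sequence reaches the identity threshold against any training
#' sequence, even through chains of similarity.
#'
#' @param proteins named character vector of sequences.
#' @param threshold percent identity at or above which two sequences are
#'   considered redundant (default 50).
#' @param train_fraction target fraction of proteins on the training side.
#' @param backend an alignment backend.
#' @return An `identity_split`: list with `train`, `test` (id vectors) and
#'   `threshold`.
#' @export
identity_split <- function(proteins, threshold = 50, train_fraction = 0.8,
                           backend = sw_backend()) {
  n <- length(proteins)
  if (n < 2L) stop("need at least two proteins to split")
  ids <- names(proteins)
  # union-find over identity edges
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (pairwise_identity(proteins[[i]], proteins[[j]], backend) >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  groups <- split(ids, comp)
  if (length(groups) < 2L)
    stop("all proteins fall in one similarity component; no valid split")
  sizes <- lengths(groups)
  ord <- order(-sizes, vapply(groups, min, ""))
  train <- character(0)
  for (g in ord) {
    if (length(train) >= train_fraction * n) break
    train <- c(train, groups[[g]])
  }
  test <- setdiff(ids, train)
  if (!length(test))  # every component was needed to reach the target
    stop("training fraction leaves no test proteins; lower train_fraction")
  structure(list(train = sort(train), test = sort(test), threshold = threshold),
            class = "identity_split")
}

#' @export
print.identity_split <- function(x, ...) {
  cat("<identity_split> ", length(x$train), " train / ", length(x$test),
      " test at <", x$threshold, "% identity\n", sep = "")
  invisible(x)
}

#' Best-hit annotation transfer (BLAST-style baseline)
#'
#' Assigns a query protein the complete propagated annotation set of its
#' highest-scoring alignment hit in the annotated training database. With no
#' hit above the backend's reporting threshold the prediction is empty. Ties
#' on the best score go to the lexicographically smallest training id, so
#' the baseline is deterministic.
#'
#' @param query a `protein_record` or sequence string.
#' @param train_seqs named character vector of training sequences.
#' @param train_ann named list: training protein -> propagated term set.
#' @param backend an alignment backend.
#' @return Character vector of transferred term ids (possibly empty).
#' @export
best_hit_transfer <- function(query, train_seqs, train_ann,
                              backend = sw_backend()) {
  if (!length(train_seqs)) stop("empty training database")
  hits <- align_scores(backend, query, train_seqs)
  if (!nrow(hits)) return(character(0))
  best <- hits[order(-hits$score, hits$id), , drop = FALSE][1, ]
  ts <- train_ann[[best$id]]
  if (is.null(ts)) character(0) else sort(unique(ts))
}

#' Run the best-hit baseline over a test set
#'
#' Convenience wrapper producing a binary prediction matrix over a selected
#' term set, directly comparable with model predictions (the baseline has no
#' score gradation: transferred terms score 1, everything else 0).
#'
#' @param queries named character vector of test sequences.
#' @param train_seqs,train_ann,backend see [best_hit_transfer()].
#' @param termset a `term_set` defining the prediction universe.
#' @return A `prediction_matrix` (see [prediction_matrix()]).
#' @export
baseline_predictions <- function(queries, train_seqs, train_ann, termset,
                                 backend = sw_backend()) {
  sets <- lapply(queries, best_hit_transfer, train_seqs = train_seqs,
                 train_ann = train_ann, backend = backend)
  names(sets) <- names(queries)
  prediction_from_sets(sets, termset)
}
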