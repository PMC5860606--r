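#' Prediction matrix container
#'
#' Scores in `[0, 1]` for each (protein, selected term) pair.
#'
#' @param scores numeric matrix, proteins x terms, rownames = protein ids.
#' @param terms ordered character vector of term ids (columns).
#' @return A `prediction_matrix`: list with `ids`, `terms`, `scores`.
#' @export
prediction_matrix <- function(scores, terms) {
  stopifnot(is.matrix(scores), ncol(scores) == length(terms),
            !is.null(rownames(scores)))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  colnames(scores) <- terms
  structure(list(ids = rownames(scores), terms = terms, scores = scores),
            class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat("<prediction_matrix> ", length(x$ids), " proteins x ",
      length(x$terms), " terms\n", sep = "")
  invisible(x)
}

#' Binary prediction matrix from per-protein term sets
#'
#' @param sets named list: protein -> predicted term ids.
#' @param termset a `term_set` (or character vector of terms).
#' @return A `prediction_matrix` with 0/1 scores.
#' @export
prediction_from_sets <- function(sets, termset) {
  terms <- if (inherits(termset, "term_set")) termset$terms else termset
  m <- matrix(0, nrow = length(sets), ncol = length(terms),
              dimnames = list(names(sets), terms))
  for (p in names(sets)) m[p, intersect(sets[[p]], terms)] <- 1
  prediction_matrix(m, terms)
}

# Align a truth annotation list with a prediction matrix -> 0/1 matrix.
# Proteins with no true term inside the universe are dropped with a warning
# (recall is undefined for them; evaluated proteins carry >= 1 annotation).
.truth_matrix <- function(pred, truth, drop_empty = TRUE) {
  Y <- matrix(0L, nrow = length(pred$ids), ncol = length(pred$terms),
              dimnames = list(pred$ids, pred$terms))
  for (p in pred$ids) Y[p, intersect(truth[[p]], pred$terms)] <- 1L
  if (drop_empty) {
    keep <- rowSums(Y) > 0L
    if (!all(keep))
      warning(sum(!keep), " protein(s) without true terms in the evaluation ",
              "universe were excluded")
    Y <- Y[keep, , drop = FALSE]
  }
  Y
}

#' Protein-centric maximum F-measure
#'
#' For each threshold t, a protein's predicted set is every term scoring at
#' least t. Precision is averaged over the m(t) proteins with a nonempty
#' prediction; recall is averaged over all n proteins. Fmax is the maximum
#' over thresholds of the harmonic mean of the two averages; thresholds where
#' no protein predicts anything contribute F = 0.
#'
#' @param pred a `prediction_matrix`.
#' @param truth named list: protein -> propagated true term set.
#' @param thresholds threshold grid (default 0, 0.01, ..., 1, the CAFA
#'   convention).
#' @return list with `fmax`, `avgpr`, `avgrc` (at the maximising threshold),
#'   `t_max` (smallest maximising threshold) and `n`.
#' @export
protein_fmax <- function(pred, truth, thresholds = seq(0, 1, by = 0.01)) {
  Y <- .truth_matrix(pred, truth)
  S <- pred$scores[rownames(Y), , drop = FALSE]
  n <- nrow(Y)
  if (n == 0L) stop("no evaluable proteins")
  ntrue <- rowSums(Y)
  best <- list(fmax = 0, avgpr = 0, avgrc = 0, t_max = thresholds[1], n = n)
  fbest <- -Inf
  for (t in thresholds) {
    P <- S >= t
    tp <- rowSums(P & (Y == 1L))
    npred <- rowSums(P)
    has <- npred > 0L
    m_t <- sum(has)
    avgpr <- if (m_t) mean(tp[has] / npred[has]) else 0
    avgrc <- mean(tp / ntrue)
    f <- if (m_t == 0L || avgpr + avgrc == 0) 0 else
      2 * avgpr * avgrc / (avgpr + avgrc)
    if (f > fbest + 1e-15) {
      fbest <- f
      best <- list(fmax = f, avgpr = avgpr, avgrc = avgrc, t_max = t, n = n)
    }
  }
  best
}

# tie-corrected rank AUC (probability a random positive outscores a random
# negative, ties counting 1/2); NA when a class is absent
.rank_auc <- function(scores, labels) {
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Term-centric ROC AUC
#'
#' AUC of sensitivity against 1 - specificity across thresholds for one term,
#' computed as the tie-corrected rank statistic (equal to trapezoidal
#' integration of the step ROC curve).
#'
#' @inheritParams protein_fmax
#' @param term term id.
#' @return AUC in `[0, 1]`, or `NA` if the term has no positive or no
#'   negative protein.
#' @export
term_auc <- function(pred, truth, term) {
  Y <- .truth_matrix(pred, truth, drop_empty = FALSE)
  .rank_auc(pred$scores[, term], Y[, term])
}

#' Term-centric maximum F-measure
#'
#' Precision/recall for one term across all proteins, maximised over
#' thresholds. Thresholds with no predicted positives contribute F = 0.
#'
#' @inheritParams term_auc
#' @param thresholds threshold grid.
#' @return Fmax for the term in `[0, 1]`.
#' @export
term_fmax <- function(pred, truth, term, thresholds = seq(0, 1, by = 0.01)) {
  Y <- .truth_matrix(pred, truth, drop_empty = FALSE)
  y <- Y[, term]; s <- pred$scores[, term]
  np <- sum(y == 1L)
  best <- 0
  for (t in thresholds) {
    p <- s >= t
    tp <- sum(p & y == 1L)
    if (tp == 0L) next
    pr <- tp / sum(p)
    rc <- tp / np
    best <- max(best, 2 * pr * rc / (pr + rc))
  }
  best
}

#' Global (micro-pooled) ROC AUC
#'
#' All (protein, term) pairs pooled into one binary classification problem.
#'
#' @inheritParams protein_fmax
#' @return AUC, or `NA` if the pool lacks a positive or a negative pair.
#' @export
global_auc <- function(pred, truth) {
  Y <- .truth_matrix(pred, truth, drop_empty = FALSE)
  .rank_auc(as.vector(pred$scores), as.vector(Y))
}

#' Matthews correlation coefficient at a threshold
#'
#' Confusion counts pooled over all (protein, term) pairs at threshold `t`;
#' a zero denominator yields 0 by convention.
#'
#' @inheritParams protein_fmax
#' @param t score threshold (typically the Fmax-maximising threshold).
#' @return MCC in `[-1, 1]`.
#' @export
mcc_at <- function(pred, truth, t) {
  Y <- .truth_matrix(pred, truth, drop_empty = FALSE)
  P <- pred$scores >= t
  tp <- sum(P & Y == 1L); fp <- sum(P & Y == 0L)
  fn <- sum(!P & Y == 1L); tn <- sum(!P & Y == 0L)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Full evaluation report
#'
#' Protein-centric Fmax with its average precision/recall and threshold,
#' per-term AUC and Fmax, global micro-pooled AUC, and MCC at the
#' Fmax-maximising threshold.
#'
#' @inheritParams protein_fmax
#' @return An `evaluation_report`: list with `fmax`, `avgpr`, `avgrc`,
#'   `t_max`, `auc`, `mcc`, `term_auc` (named, NA where undefined),
#'   `term_fmax` (named) and `n`.
#' @export
evaluate_predictions <- function(pred, truth, thresholds = seq(0, 1, by = 0.01)) {
  pf <- protein_fmax(pred, truth, thresholds)
  Y <- .truth_matrix(pred, truth, drop_empty = FALSE)
  tauc <- vapply(pred$terms, function(tm) .rank_auc(pred$scores[, tm], Y[, tm]),
                 1.0)
  tfm <- vapply(pred$terms, function(tm) term_fmax(pred, truth, tm, thresholds),
                1.0)
  structure(list(fmax = pf$fmax, avgpr = pf$avgpr, avgrc = pf$avgrc,
                 t_max = pf$t_max, auc = global_auc(pred, truth),
                 mcc = mcc_at(pred, truth, pf$t_max),
                 term_auc = tauc, term_fmax = tfm, n = pf$n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Fmax %.3f  AvgPr %.3f  AvgRc %.3f  AUC %.3f  MCC %.3f  (t = %.2f, n = %d)\n",
              x$fmax, x$avgpr, x$avgrc, x$auc, x$mcc, x$t_max, x$n))
  invisible(x)
}

#' Evaluation stratified by protein groups
#'
#' Runs the full metric suite independently on each group of proteins (for
#' example per organism or per protein family). Groups with no evaluable
#' protein are skipped with a warning.
#'
#' @inheritParams protein_fmax
#' @param grouping named character vector: protein id -> group key.
#' @return Named list of `evaluation_report`s, one per group.
#' @export
evaluate_grouped <- function(pred, truth, grouping,
                             thresholds = seq(0, 1, by = 0.01)) {
  keys <- unique(grouping[pred$ids])
  out <- list()
  for (g in keys) {
    ids <- pred$ids[grouping[pred$ids] == g]
    if (!length(ids)) { warning("empty group ", g, " skipped"); next }
    sub <- prediction_matrix(pred$scores[ids, , drop = FALSE], pred$terms)
    out[[g]] <- evaluate_predictions(sub, truth[ids], thresholds)
  }
  out
}

#' Read / write prediction TSV (protein, term, score)
#'
#' @param pred a `prediction_matrix`.
#' @param path file path.
#' @param min_score rows below this score are not written.
#' @return `path` invisibly (write); a `prediction_matrix` (read).
#' @export
write_predictions <- function(pred, path, min_score = 0) {
  i <- which(pred$scores >= min_score, arr.ind = TRUE)
  df <- data.frame(protein = pred$ids[i[, 1]], term = pred$terms[i[, 2]],
                   score = pred$scores[i])
  df <- df[order(df$protein, df$term), ]
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @param terms term universe for the matrix (defaults to terms present).
#' @export
read_predictions <- function(path, terms = NULL) {
  df <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE,
                          col.names = c("protein", "term", "score"))
  ids <- sort(unique(df$protein))
  if (is.null(terms)) terms <- sort(unique(df$term))
  m <- matrix(0, nrow = length(ids), ncol = length(terms),
              dimnames = list(ids, terms))
  keep <- df$term %in% terms
  m[cbind(match(df$protein[keep], ids), match(df$term[keep], terms))] <-
    df$score[keep]
  prediction_matrix(m, terms)
}
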