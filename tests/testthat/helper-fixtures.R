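# Text fixtures and independent brute-force oracles used across the suite.

obo_chain <- function() c(
  "format-version: 1.2", "",
  "[Term]", "id: GO:0000001", "name: a", "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "name: b", "namespace: biological_process",
  "is_a: GO:0000001 ! a", "",
  "[Term]", "id: GO:0000003", "name: c", "namespace: biological_process",
  "is_a: GO:0000002 ! b", "")

obo_diamond <- function() c(
  "format-version: 1.2", "",
  "[Term]", "id: GO:0000001", "name: a", "namespace: biological_process", "",
  "[Term]", "id: GO:0000002", "name: b", "namespace: biological_process",
  "is_a: GO:0000001", "",
  "[Term]", "id: GO:0000003", "name: c", "namespace: biological_process",
  "is_a: GO:0000001", "",
  "[Term]", "id: GO:0000004", "name: d", "namespace: biological_process",
  "is_a: GO:0000002", "is_a: GO:0000003", "")

# random DAG constructed independently of the package's toy generator:
# term i > 1 draws 1-2 parents among earlier terms
random_dag <- function(n, seed, p_two = 0.4) {
  set.seed(seed)
  ids <- sprintf("RND:%04d", seq_len(n))
  parents <- rep(list(character(0)), n)
  names(parents) <- ids
  for (i in seq_len(n)[-1]) {
    k <- 1L + (runif(1) < p_two && i > 2L)
    parents[[ids[i]]] <- ids[sample.int(i - 1L, min(k, i - 1L))]
  }
  structure(list(terms = ids,
                 name = stats::setNames(ids, ids),
                 namespace = stats::setNames(rep("BP", n), ids),
                 parents = parents, obsolete = character(0),
                 alt = stats::setNames(character(0), character(0))),
            class = "ontology_dag")
}

# ancestors by repeated one-step parent expansion until fixed point
naive_ancestors <- function(dag, term) {
  out <- character(0)
  frontier <- term
  repeat {
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    if (!length(nxt)) break
    out <- union(out, nxt)
    frontier <- nxt
  }
  sort(out)
}

# closure-max oracle: merged(t) = max raw over selected descendants of t + t
closure_max_oracle <- function(raw, dag, selected) {
  vapply(selected, function(t) {
    descs <- selected[vapply(selected, function(d)
      d == t || t %in% naive_ancestors(dag, d), TRUE)]
    max(raw[descs])
  }, 1.0)
}

# protein-centric Fmax by direct enumeration (no vectorisation shared with
# the implementation)
fmax_oracle <- function(S, Y, thresholds) {
  n <- nrow(S)
  best <- 0
  for (t in thresholds) {
    prs <- c(); rcs <- c()
    for (i in seq_len(n)) {
      P <- which(S[i, ] >= t)
      T_i <- which(Y[i, ] == 1)
      tp <- length(intersect(P, T_i))
      if (length(P) > 0) prs <- c(prs, tp / length(P))
      rcs <- c(rcs, tp / length(T_i))
    }
    if (!length(prs)) next
    avgpr <- mean(prs); avgrc <- mean(rcs)
    if (avgpr + avgrc > 0) best <- max(best, 2 * avgpr * avgrc / (avgpr + avgrc))
  }
  best
}

# all-pairs rank AUC with ties counting 1/2
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

term_fmax_oracle <- function(scores, labels, thresholds) {
  best <- 0
  for (t in thresholds) {
    pp <- which(scores >= t)
    tp <- sum(labels[pp] == 1)
    if (tp == 0) next
    pr <- tp / length(pp); rc <- tp / sum(labels == 1)
    best <- max(best, 2 * pr * rc / (pr + rc))
  }
  best
}

mcc_oracle <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# affine-gap Smith-Waterman on short strings, straight from the recurrences
sw_oracle <- function(a, b, gap_open = 11, gap_extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)   # match/mismatch state
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (vertical)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a (horizontal)
  best <- 0; besti <- 0; bestj <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                           X[i, j + 1] - gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                           Y[i + 1, j] - gap_extend)
    sc <- sub[A[i], B[j]]
    M[i + 1, j + 1] <- max(0,
                           max(M[i, j], X[i, j], Y[i, j]) + sc)
    if (M[i + 1, j + 1] > best) {
      best <- M[i + 1, j + 1]; besti <- i; bestj <- j
    }
  }
  # traceback for identity over alignment length
  matches <- 0L; len <- 0L
  i <- besti; j <- bestj; state <- "M"
  while (i > 0 && j > 0) {
    if (state == "M") {
      if (M[i + 1, j + 1] == 0) break
      sc <- sub[A[i], B[j]]
      len <- len + 1L
      if (A[i] == B[j]) matches <- matches + 1L
      prev <- M[i + 1, j + 1] - sc
      if (prev == M[i, j]) { i <- i - 1; j <- j - 1 }
      else if (prev == X[i, j]) { i <- i - 1; j <- j - 1; state <- "X" }
      else { i <- i - 1; j <- j - 1; state <- "Y" }
    } else if (state == "X") {
      len <- len + 1L
      if (X[i + 1, j + 1] == M[i, j + 1] - 11 - 1) state <- "M"
      i <- i - 1
    } else {
      len <- len + 1L
      if (Y[i + 1, j + 1] == M[i + 1, j] - 11 - 1) state <- "M"
      j <- j - 1
    }
  }
  list(score = best, matches = matches, length = len,
       pident = if (len > 0) 100 * matches / len else 0)
}

# a seeded random protein sequence over the canonical alphabet
random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# a tiny trained model shared by model-level tests (built lazily, cached)
.tiny_cache <- new.env()
tiny_trained <- function() {
  if (!is.null(.tiny_cache$model)) return(.tiny_cache$fixture)
  ds <- make_synthetic_dataset(synthetic_spec(n_proteins = 150L, seed = 42L))
  samples <- encode_dataset(ds$proteins, ds$termset, ds$annotations,
                            ds$embeddings)
  model <- build_model(model_spec(), ds$termset, ds$dag)
  model <- train_model(model, samples,
                       train_config(max_epochs = 4L, seed = 3L))
  .tiny_cache$model <- model
  .tiny_cache$fixture <- list(ds = ds, samples = samples, model = model)
  .tiny_cache$fixture
}
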