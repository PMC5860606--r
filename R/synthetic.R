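# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic benchmark dataset
#'
#' Defines a fully self-contained toy problem: a rooted DAG ontology with a
#' fixed number of leaf classes, proteins whose membership in each leaf is
#' signalled by a planted sequence motif, and network-embedding vectors
#' correlated with the protein's classes. All randomness derives from `seed`
#' through R's Mersenne-Twister generator, so every artefact is reproducible
#' across platforms.
#'
#' @param n_terms total ontology terms (root + internal + leaves).
#' @param n_leaves number of motif-bearing leaf classes.
#' @param max_parents maximum number of parents of a non-root term (1-2).
#' @param n_proteins number of proteins to generate.
#' @param seq_length integer range `c(min, max)` of sequence lengths.
#' @param motif_length residue length of each planted motif (>= 5).
#' @param motif_prob probability that a positive protein actually carries the
#'   leaf's motif (the 10% complement behaves as label noise).
#' @param leaf_prevalence per-leaf membership probability.
#' @param embed_dim embedding dimension.
#' @param embed_noise standard deviation of the isotropic noise added to the
#'   class-prototype sum.
#' @param seed integer master seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_terms = 13L, n_leaves = 8L, max_parents = 2L,
                           n_proteins = 2500L, seq_length = c(50L, 100L),
                           motif_length = 8L, motif_prob = 0.9,
                           leaf_prevalence = 0.3, embed_dim = 256L,
                           embed_noise = 0.1, seed = 1L) {
  stopifnot(n_terms >= 1L, n_leaves >= 1L, n_terms > n_leaves || n_terms == 1L,
            motif_length >= 5L, seq_length[1] >= motif_length,
            seq_length[2] <= SEQ_MAX_LENGTH, max_parents %in% 1:2)
  structure(list(n_terms = as.integer(n_terms), n_leaves = as.integer(n_leaves),
                 max_parents = as.integer(max_parents),
                 n_proteins = as.integer(n_proteins),
                 seq_length = as.integer(seq_length),
                 motif_length = as.integer(motif_length),
                 motif_prob = motif_prob, leaf_prevalence = leaf_prevalence,
                 embed_dim = as.integer(embed_dim), embed_noise = embed_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.toy_id <- function(i) sprintf("TOY:%07d", i)

#' Generate a toy ontology DAG
#'
#' A rooted, single-namespace DAG: internal terms are attached to 1-2 earlier
#' terms (guaranteeing acyclicity and reachability from the root), then
#' exactly `n_leaves` leaf terms are attached to 1-2 internal/root terms.
#' Deterministic under the spec seed.
#'
#' @param spec a `synthetic_spec`.
#' @return An `ontology_dag` with namespace `"BP"` for every term.
#' @export
make_toy_ontology <- function(spec) {
  .with_seed(spec$seed, {
    n <- spec$n_terms
    ids <- .toy_id(seq_len(n))
    parents <- rep(list(character(0)), n); names(parents) <- ids
    if (n > 1L) {
      n_int <- n - spec$n_leaves  # root + internals
      for (i in seq(2L, length.out = max(0L, n_int - 1L))) {
        k <- sample(seq_len(spec$max_parents), 1L)
        parents[[ids[i]]] <- ids[sample.int(i - 1L, min(k, i - 1L))]
      }
      hubs <- seq_len(max(1L, n_int))
      # internals that have no child yet must each anchor a leaf, otherwise
      # they would surface as extra (motif-less) leaves of the DAG
      with_child <- unique(unlist(parents, use.names = FALSE))
      childless <- setdiff(ids[hubs], c(with_child, if (n_int > 1L) ids[1]))
      if (length(childless) > spec$n_leaves)
        stop("toy DAG needs n_leaves >= ", length(childless),
             " to keep every internal term internal")
      for (j in seq_len(spec$n_leaves)) {
        i <- n_int + j
        k <- sample(seq_len(spec$max_parents), 1L)
        ps <- ids[sample(hubs, min(k, length(hubs)))]
        if (j <= length(childless)) ps <- unique(c(childless[j], ps))[seq_len(min(k, length(hubs)))]
        parents[[ids[i]]] <- ps
      }
    }
    nms <- paste("toy term", seq_len(n)); names(nms) <- ids
    nss <- rep("BP", n); names(nss) <- ids
    structure(list(terms = ids, name = nms, namespace = nss, parents = parents,
                   obsolete = character(0),
                   alt = stats::setNames(character(0), character(0))),
              class = "ontology_dag")
  })
}

#' Leaves of an ontology DAG
#'
#' Terms that are nobody's parent; in the synthetic benchmark these are the
#' motif-bearing classes.
#'
#' @param dag an `ontology_dag`.
#' @return Character vector of leaf term ids.
#' @export
dag_leaves <- function(dag) {
  setdiff(dag$terms, unique(unlist(dag$parents, use.names = FALSE)))
}

#' Generate motif-planted proteins with consistent annotations
#'
#' Each protein independently joins every leaf class with probability
#' `leaf_prevalence` (resampled until it carries at least one leaf, mirroring
#' the requirement that trained/evaluated proteins have at least one
#' annotation). For every joined leaf, its class motif is written into the
#' sequence at a random position with probability `motif_prob`; the remaining
#' residues are i.i.d. uniform over the 20-letter alphabet. Annotations are
#' the joined leaves propagated up the DAG.
#'
#' @param spec a `synthetic_spec`.
#' @param dag the toy ontology from [make_toy_ontology()].
#' @return list with `proteins` (named character vector of sequences),
#'   `annotations` (propagated, named list) and `motifs` (named character
#'   vector leaf -> motif).
#' @export
make_proteins <- function(spec, dag) {
  leaves <- sort(dag_leaves(dag))
  .with_seed(spec$seed + 1L, {
    # pairwise-distinct motifs over the canonical alphabet
    repeat {
      motifs <- vapply(leaves, function(...) paste(
        sample(.aa_chars, spec$motif_length, replace = TRUE), collapse = ""), "")
      if (!anyDuplicated(motifs)) break
    }
    if (spec$motif_length > spec$seq_length[1])
      stop("motif longer than the shortest sequence")
    ids <- sprintf("SYN%05d", seq_len(spec$n_proteins))
    seqs <- character(spec$n_proteins)
    leafsets <- vector("list", spec$n_proteins)
    for (i in seq_len(spec$n_proteins)) {
      repeat {
        memb <- stats::runif(length(leaves)) < spec$leaf_prevalence
        if (any(memb)) break
      }
      L <- sample(seq(spec$seq_length[1], spec$seq_length[2]), 1L)
      s <- sample(.aa_chars, L, replace = TRUE)
      m <- spec$motif_length
      occupied <- logical(L)
      for (lf in leaves[memb]) {
        if (stats::runif(1) < spec$motif_prob) {
          # prefer a slot that does not clobber an already planted motif;
          # if none is free the motifs overlap (rare, accepted label noise)
          free <- which(vapply(seq_len(L - m + 1L), function(st)
            !any(occupied[st:(st + m - 1L)]), TRUE))
          start <- if (length(free)) free[sample.int(length(free), 1L)] else
            sample.int(L - m + 1L, 1L)
          s[seq(start, length.out = m)] <- strsplit(motifs[[lf]], "")[[1]]
          occupied[seq(start, length.out = m)] <- TRUE
        }
      }
      seqs[i] <- paste(s, collapse = "")
      leafsets[[i]] <- leaves[memb]
    }
    names(seqs) <- ids
    names(leafsets) <- ids
    ann <- propagate_annotations(dag, leafsets)
    list(proteins = seqs, annotations = ann, motifs = motifs)
  })
}

#' Generate class-correlated network embeddings
#'
#' Each selected term gets a fixed Gaussian prototype vector; a protein's
#' embedding is the sum of the prototypes of its selected (propagated) terms
#' plus isotropic Gaussian noise. This emulates network embeddings that carry
#' functional signal, the regime in which fusing network features should help
#' the classifier.
#'
#' @param spec a `synthetic_spec`.
#' @param annotations propagated annotations (named list).
#' @param termset a `term_set` (prototypes are created for its terms).
#' @return An `embedding_table` covering every annotated protein.
#' @export
make_embeddings <- function(spec, annotations, termset) {
  protos <- .with_seed(spec$seed + 2L,
    matrix(stats::rnorm(length(termset$terms) * spec$embed_dim, sd = 0.5),
           nrow = length(termset$terms), ncol = spec$embed_dim,
           dimnames = list(termset$terms, NULL)))
  .with_seed(spec$seed + 3L, {
    m <- matrix(0, nrow = length(annotations), ncol = spec$embed_dim,
                dimnames = list(names(annotations), NULL))
    for (p in names(annotations)) {
      sel <- intersect(annotations[[p]], termset$terms)
      v <- if (length(sel)) colSums(protos[sel, , drop = FALSE]) else
        numeric(spec$embed_dim)
      m[p, ] <- v + stats::rnorm(spec$embed_dim, sd = spec$embed_noise)
    }
    embedding_table(m)
  })
}

#' Materialise a complete synthetic dataset
#'
#' Generates the toy ontology, the proteins and their annotations, selects
#' the term set over all generated annotations, and builds class-correlated
#' embeddings. This is the package's standard desk-scale benchmark input.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `dag`, `proteins`, `annotations`, `motifs`, `termset`,
#'   `embeddings` and the `spec` itself.
#' @export
make_synthetic_dataset <- function(spec = synthetic_spec()) {
  dag <- make_toy_ontology(spec)
  pr <- make_proteins(spec, dag)
  termset <- select_terms(dag, pr$annotations, branch = "BP",
                          top_k = spec$n_terms, min_count = 1L)
  emb <- make_embeddings(spec, pr$annotations, termset)
  list(dag = dag, proteins = pr$proteins, annotations = pr$annotations,
       motifs = pr$motifs, termset = termset, embeddings = emb, spec = spec)
}
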