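test_that("toy ontologies are rooted, acyclic DAGs, deterministic under seed", {
  expect_length(make_toy_ontology(synthetic_spec(n_terms = 1L, n_leaves = 1L))$parents[[1]], 0L)

  s <- synthetic_spec(seed = 3L)
  d1 <- make_toy_ontology(s)
  d2 <- make_toy_ontology(s)
  expect_identical(d1$parents, d2$parents)

  for (seed in 1:6) {
    spec <- synthetic_spec(n_terms = 30L, n_leaves = 18L, seed = seed)
    dag <- make_toy_ontology(spec)
    root <- dag$terms[lengths(dag$parents) == 0]
    expect_length(root, 1L)  # rooted
    # acyclic + every term reaches the root (graph oracle on ancestors)
    for (t in setdiff(dag$terms, root))
      expect_true(root %in% naive_ancestors(dag, t))
    # every non-root has 1-2 parents
    expect_true(all(lengths(dag$parents[setdiff(dag$terms, root)]) %in% 1:2))
    # exactly the requested number of leaves
    expect_length(dag_leaves(dag), 18L)
  }
})

test_that("generated proteins satisfy every validation rule and plant motifs", {
  spec <- synthetic_spec(n_proteins = 80L, motif_prob = 1, seed = 8L)
  dag <- make_toy_ontology(spec)
  pr <- make_proteins(spec, dag)
  expect_length(pr$proteins, 80L)

  val <- validate_proteins(pr$proteins)
  expect_equal(nrow(val$dropped), 0L)  # all pass length + alphabet rules

  # with insertion probability 1, every positive carries its leaf motif
  # whenever the motifs fit without overlap (single-leaf proteins always do)
  leaves <- dag_leaves(dag)
  carried <- 0L; positives <- 0L
  for (p in names(pr$proteins)) {
    mine <- intersect(pr$annotations[[p]], leaves)
    hits <- vapply(mine, function(lf)
      grepl(pr$motifs[[lf]], pr$proteins[[p]], fixed = TRUE), TRUE)
    positives <- positives + length(mine); carried <- carried + sum(hits)
    if (length(mine) == 1L) expect_true(hits)
  }
  expect_gt(carried / positives, 0.95)

  # motifs are pairwise distinct and long enough
  expect_equal(anyDuplicated(pr$motifs), 0L)
  expect_true(all(nchar(pr$motifs) >= 5L))

  # annotations are propagated (upward closed)
  for (p in sample(names(pr$annotations), 10))
    for (t in pr$annotations[[p]])
      expect_true(all(naive_ancestors(dag, t) %in% pr$annotations[[p]]))

  # empty protein set gives empty outputs
  spec0 <- synthetic_spec(n_proteins = 0L, seed = 8L)
  pr0 <- make_proteins(spec0, dag)
  expect_length(pr0$proteins, 0L)
  expect_length(pr0$annotations, 0L)
})

test_that("leaf prevalence lands within three standard errors of its target", {
  spec <- synthetic_spec(n_proteins = 2000L, leaf_prevalence = 0.3, seed = 13L)
  dag <- make_toy_ontology(spec)
  pr <- make_proteins(spec, dag)
  leaves <- dag_leaves(dag)
  member <- vapply(pr$annotations, function(ts) length(intersect(ts, leaves)),
                   1L)
  phat <- sum(member) / (2000 * length(leaves))
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("embeddings are prototype sums plus seeded noise", {
  dag <- parse_obo(obo_diamond())
  ts <- term_set(dag, dag$terms)
  ann <- propagate_annotations(dag, list(p1 = "GO:0000004", p2 = "GO:0000004",
                                         p3 = "GO:0000002"))
  spec <- synthetic_spec(embed_noise = 0, seed = 17L)
  tab <- make_embeddings(spec, ann, ts)
  v <- embedding_vectors(tab, c("p1", "p2", "p3"))
  # zero noise, identical annotation sets -> identical vectors
  expect_equal(v["p1", ], v["p2", ])

  # vector difference equals the prototype-sum difference computed directly:
  # p1 carries the diamond closure, p3 only {root, B}; the difference is the
  # C + D prototype sum
  spec2 <- synthetic_spec(embed_noise = 0, seed = 17L)
  ann_cd <- propagate_annotations(dag, list(q = "GO:0000004"))
  ann_b <- propagate_annotations(dag, list(q = "GO:0000002"))
  t_cd <- embedding_vectors(make_embeddings(spec2, ann_cd, ts), "q")
  t_b <- embedding_vectors(make_embeddings(spec2, ann_b, ts), "q")
  expect_equal(v["p1", ] - v["p3", ], t_cd[1, ] - t_b[1, ], tolerance = 1e-12)

  # determinism and the zero-fallback path for omitted proteins
  tab2 <- make_embeddings(spec, ann, ts)
  expect_identical(tab$vectors, tab2$vectors)
  expect_equal(unname(embedding_vectors(tab, "absent")[1, ]), rep(0, 256))
})

test_that("the bundled dataset round-trips through the standard formats", {
  cfg <- run_config(seed = 19L, out_dir = withr::local_tempdir())
  ds <- cmd_synth(cfg, synthetic_spec(n_proteins = 40L, seed = 19L))
  dag <- parse_obo(file.path(cfg$out_dir, "ontology.obo"))
  expect_setequal(dag$terms, ds$dag$terms)
  seqs <- read_fasta(file.path(cfg$out_dir, "proteins.fasta"))
  expect_identical(seqs[names(ds$proteins)], ds$proteins)
  ann <- read_annotations(file.path(cfg$out_dir, "annotations.tsv"))
  prop <- propagate_annotations(dag, ann)
  expect_identical(prop, ds$annotations[names(prop)])
  emb <- load_embeddings(file.path(cfg$out_dir, "embeddings.tsv"))
  expect_equal(emb$vectors[names(ds$proteins)[1], ],
               ds$embeddings$vectors[names(ds$proteins)[1], ],
               tolerance = 1e-12, ignore_attr = TRUE)
})
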