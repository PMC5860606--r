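test_that("parse_obo reads stanzas, edges, alt ids and obsolescence", {
  expect_length(parse_obo("format-version: 1.2")$terms, 0L)

  dag <- parse_obo(obo_chain())
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(dag$parents[["GO:0000003"]], "GO:0000002")
  expect_equal(dag$parents[["GO:0000002"]], "GO:0000001")
  expect_equal(unname(dag$namespace["GO:0000001"]), "BP")
  expect_equal(unname(dag$name["GO:0000002"]), "b")

  dag2 <- parse_obo(c(obo_chain(),
                      "[Term]", "id: GO:0000009", "alt_id: GO:0000010",
                      "is_a: GO:0000001", "",
                      "[Term]", "id: GO:0000008", "is_obsolete: true",
                      "is_a: GO:0000001", ""))
  expect_equal(unname(dag2$alt["GO:0000010"]), "GO:0000009")
  expect_true("GO:0000008" %in% dag2$obsolete)
  # obsolete terms keep no outgoing propagation edges
  expect_length(dag2$parents[["GO:0000008"]], 0L)
})

test_that("parse_obo rejects dangling parents and cycles", {
  expect_error(parse_obo(c("[Term]", "id: A", "is_a: MISSING", "")),
               "unknown term")
  expect_error(parse_obo(c("[Term]", "id: A", "is_a: B", "",
                           "[Term]", "id: B", "is_a: A", "")),
               "cyclic")
})

test_that("ancestors walks is_a transitively and rejects unknown terms", {
  dag <- parse_obo(obo_chain())
  expect_equal(ancestors(dag, "GO:0000001"), character(0))
  expect_setequal(ancestors(dag, "GO:0000003"), c("GO:0000001", "GO:0000002"))
  expect_error(ancestors(dag, "GO:9999999"), "GO:9999999")

  dd <- parse_obo(obo_diamond())
  expect_setequal(ancestors(dd, "GO:0000004"),
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
})

test_that("ancestors and ancestors_all match the repeated-expansion oracle", {
  for (seed in 1:8) {
    dag <- random_dag(50, seed)
    anc <- ancestors_all(dag)
    for (t in sample(dag$terms, 12)) {
      expect_equal(ancestors(dag, t), naive_ancestors(dag, t), info = t)
      expect_equal(anc[[t]], naive_ancestors(dag, t), info = t)
    }
  }
})

test_that("propagation closes annotation sets upward and is idempotent", {
  dag <- parse_obo(obo_chain())
  ann <- list(p1 = "GO:0000001", p2 = "GO:0000003")
  prop <- propagate_annotations(dag, ann)
  expect_equal(prop$p1, "GO:0000001")  # root-only annotation is unchanged
  expect_setequal(prop$p2, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_identical(propagate_annotations(dag, prop), prop)

  dd <- parse_obo(obo_diamond())
  expect_setequal(propagate_annotations(dd, list(p = "GO:0000004"))$p,
                  c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"))

  # property: membership of t implies membership of every ancestor of t
  for (seed in 1:5) {
    dag <- random_dag(40, seed + 100)
    ann <- lapply(1:10, function(i) sample(dag$terms, 3))
    names(ann) <- paste0("p", 1:10)
    prop <- propagate_annotations(dag, ann)
    expect_identical(propagate_annotations(dag, prop), prop)
    for (p in names(prop)) for (t in prop[[p]])
      expect_true(all(naive_ancestors(dag, t) %in% prop[[p]]))
  }
})

test_that("propagation rewrites alt ids and refuses obsolete terms", {
  dag <- parse_obo(c(obo_chain(),
                     "[Term]", "id: GO:0000005", "is_a: GO:0000003",
                     "alt_id: GO:0000055", "",
                     "[Term]", "id: GO:0000006", "is_obsolete: true", ""))
  prop <- propagate_annotations(dag, list(p = "GO:0000055"))
  expect_true("GO:0000005" %in% prop$p)
  expect_false("GO:0000055" %in% prop$p)
  expect_error(propagate_annotations(dag, list(p = "GO:0000006")), "obsolete")
  expect_warning(out <- propagate_annotations(dag, list(p = c("GO:0000006", "GO:0000001")),
                                              lenient = TRUE), "obsolete")
  expect_equal(out$p, "GO:0000001")
})

test_that("select_terms ranks by count with lexicographic tie-break", {
  dag <- parse_obo(obo_chain())
  # counts after propagation: root 3, mid 2, leaf 1
  ann <- propagate_annotations(dag, list(a = "GO:0000003", b = "GO:0000002",
                                         c = "GO:0000001"))
  ts <- select_terms(dag, ann, "BP", top_k = 2, min_count = 1)
  expect_equal(ts$terms, c("GO:0000001", "GO:0000002"))
  expect_equal(unname(ts$index[ts$terms]), 0:1)
  expect_error(select_terms(dag, ann, "BP", top_k = 0), "top_k")
  expect_error(select_terms(dag, ann, "BP", top_k = 3, min_count = 99),
               "min_count")

  # tie at the cutoff resolved by ascending term id
  dag2 <- parse_obo(c("[Term]", "id: GO:0000002", "namespace: biological_process", "",
                      "[Term]", "id: GO:0000001", "namespace: biological_process", ""))
  ann2 <- list(p1 = c("GO:0000001", "GO:0000002"), p2 = c("GO:0000001", "GO:0000002"))
  ts2 <- select_terms(dag2, ann2, "BP", top_k = 1)
  expect_equal(ts2$terms, "GO:0000001")

  # random counts agree with a sort-then-filter oracle
  set.seed(9)
  dag3 <- random_dag(30, 77)
  prot <- paste0("q", 1:60)
  ann3 <- lapply(prot, function(p) sample(dag3$terms, sample(1:5, 1)))
  names(ann3) <- prot
  prop3 <- propagate_annotations(dag3, ann3)
  ts3 <- select_terms(dag3, prop3, "BP", top_k = 5, min_count = 2)
  cnt <- table(factor(unlist(prop3), levels = dag3$terms))
  ord <- names(cnt)[order(-as.integer(cnt), names(cnt))]
  oracle <- head(ord, 5)
  oracle <- oracle[cnt[oracle] >= 2]
  expect_equal(ts3$terms, oracle)
  expect_lte(length(ts3$terms), 5)
  expect_true(all(ts3$counts >= 2))
})

test_that("term sets partition into leaves and internal nodes", {
  dd <- parse_obo(obo_diamond())
  ts <- term_set(dd, dd$terms)
  expect_setequal(ts$leaves, "GO:0000004")
  expect_setequal(ts$internal, c("GO:0000001", "GO:0000002", "GO:0000003"))
  # leaf/internal is relative to the selected subset
  ts2 <- term_set(dd, c("GO:0000001", "GO:0000002"))
  expect_setequal(ts2$leaves, "GO:0000002")
})

test_that("topological_order puts children before parents", {
  dag <- parse_obo(obo_chain())
  expect_equal(topological_order(dag, term_set(dag, "GO:0000002")),
               "GO:0000002")
  expect_equal(topological_order(dag, term_set(dag, dag$terms)),
               c("GO:0000003", "GO:0000002", "GO:0000001"))
  for (seed in 1:5) {
    dag <- random_dag(25, seed + 300)
    sel <- sort(sample(dag$terms, 15))
    ord <- topological_order(dag, sel)
    expect_setequal(ord, sel)
    pos <- stats::setNames(seq_along(ord), ord)
    for (d in sel) for (a in intersect(naive_ancestors(dag, d), sel))
      expect_lt(pos[d], pos[a])
  }
})

test_that("obo round-trips through write_obo", {
  dag <- make_toy_ontology(synthetic_spec(seed = 5L))
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, f)
  back <- parse_obo(f)
  expect_setequal(back$terms, dag$terms)
  expect_identical(lapply(back$parents[dag$terms], sort),
                   lapply(dag$parents[dag$terms], sort))
  expect_equal(back$namespace, dag$namespace)
})
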