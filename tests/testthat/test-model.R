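test_that("architecture arithmetic reproduces the published constants", {
  spec <- model_spec()
  expect_equal(spec$shapes$embedded, c(1000L, 128L))
  expect_equal(spec$shapes$pooled_windows, 26L)
  expect_equal(spec$shapes$flattened, 832L)
  expect_equal(spec$shapes$fused, 832L + 256L)
  expect_equal(model_spec(variant = "deepgoseq")$shapes$fused, 832L)

  # non-positive shape arithmetic is rejected at spec construction
  expect_error(model_spec(seq_positions = 100L, conv_kernel = 128L),
               "non-positive")
  expect_error(model_spec(seq_positions = 150L, pool_window = 64L,
                          pool_stride = 32L, conv_kernel = 128L),
               "non-positive")
})

test_that("merge_scores takes the max over each descendant closure", {
  dag <- parse_obo(obo_chain())
  ts <- term_set(dag, c("GO:0000001", "GO:0000002"))
  raw <- c("GO:0000001" = 0.2, "GO:0000002" = 0.9)
  merged <- merge_scores(raw, ts, dag)
  expect_equal(unname(merged["GO:0000001"]), 0.9)
  expect_equal(unname(merged["GO:0000002"]), 0.9)

  flat <- c("GO:0000001" = 0.4, "GO:0000002" = 0.4)
  expect_equal(merge_scores(flat, ts, dag), flat[ts$terms])
})

test_that("merge_scores equals the closure-max oracle on random DAGs", {
  for (seed in 1:25) {
    dag <- random_dag(30, seed + 2500)
    sel <- sort(sample(dag$terms, sample(5:30, 1)))
    ts <- term_set(dag, sel)
    set.seed(seed)
    raw <- stats::setNames(runif(length(sel)), sel)
    expect_equal(merge_scores(raw, ts, dag)[sel],
                 closure_max_oracle(raw, dag, sel)[sel],
                 tolerance = 1e-15, info = seed)
    # matrix interface agrees with the vector interface
    m <- matrix(raw[ts$terms], nrow = 1, dimnames = list("p", ts$terms))
    expect_equal(merge_scores(m, ts, dag)["p", ts$terms],
                 merge_scores(raw, ts, dag)[ts$terms])
  }
})

test_that("training descends on an overfit-able toy set and is reproducible", {
  fx <- tiny_trained()
  # 50-sample toy set, 20 epochs: the data is memorisable, so the final
  # training loss must undercut the initial one
  toy <- subset_samples(fx$samples, fx$samples$ids[1:50])
  mt <- train_model(build_model(model_spec(), fx$ds$termset, fx$ds$dag),
                    toy, train_config(max_epochs = 20L, seed = 3L))
  expect_lt(mt$history[20, "train_loss"], mt$history[1, "train_loss"])
  expect_equal(fx$model$best_epoch,
               unname(which.min(fx$model$history[, "val_loss"])))

  # identical seeds give identical histories and weights
  small <- subset_samples(fx$samples, fx$samples$ids[1:60])
  cfg <- train_config(max_epochs = 2L, seed = 9L)
  m1 <- train_model(build_model(model_spec(), fx$ds$termset, fx$ds$dag),
                    small, cfg)
  m2 <- train_model(build_model(model_spec(), fx$ds$termset, fx$ds$dag),
                    small, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights$Wd, m2$weights$Wd)
  expect_identical(m1$weights$Et, m2$weights$Et)
})

test_that("hierarchical predictions are consistent, flat ones need not be", {
  fx <- tiny_trained()
  te <- subset_samples(fx$samples, fx$samples$ids[1:40])
  pred <- predict(fx$model, te)
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
  expect_equal(nrow(check_hierarchy(pred, fx$ds$termset, fx$ds$dag)), 0L)

  # thresholded prediction sets are upward-closed at any threshold
  anc <- ancestors_all(fx$ds$dag)
  for (t in c(0.1, 0.5, 0.9)) {
    P <- pred$scores >= t
    for (tm in fx$ds$termset$terms) {
      for (a in intersect(anc[[tm]], fx$ds$termset$terms))
        expect_true(all(!P[, tm] | P[, a]))
    }
  }

  # a partially trained flat model produces score inversions (permitted for
  # this variant) and the consistency checker flags them
  flat <- build_model(model_spec(variant = "deepgoflat"),
                      fx$ds$termset, fx$ds$dag)
  flat <- train_model(flat, fx$samples, train_config(max_epochs = 3L, seed = 2L))
  fpred <- predict(flat, fx$samples)
  expect_gt(nrow(check_hierarchy(fpred, fx$ds$termset, fx$ds$dag)), 0L)
})

test_that("degenerate and batched inputs behave predictably", {
  fx <- tiny_trained()
  # all-padding sequence with zero embedding: finite scores in [0, 1]
  degen <- structure(list(ids = "none",
                          indices = matrix(0L, 1, 1000),
                          net = matrix(0, 1, 256), labels = NULL),
                     class = "encoded_samples")
  p <- predict(fx$model, degen)
  expect_true(all(is.finite(p$scores)))
  expect_true(all(p$scores >= 0 & p$scores <= 1))

  # batched execution identical to single-sample execution
  te <- subset_samples(fx$samples, fx$samples$ids[11:20])
  batch <- predict(fx$model, te)$scores
  single <- do.call(rbind, lapply(te$ids, function(id)
    predict(fx$model, subset_samples(te, id))$scores))
  expect_identical(unname(batch), unname(single))
})

test_that("the deepgoseq variant ignores network embeddings", {
  fx <- tiny_trained()
  small <- subset_samples(fx$samples, fx$samples$ids[1:60])
  m <- train_model(build_model(model_spec(variant = "deepgoseq"),
                               fx$ds$termset, fx$ds$dag),
                   small, train_config(max_epochs = 2L, seed = 7L))
  te <- subset_samples(fx$samples, fx$samples$ids[61:70])
  p1 <- predict(m, te)$scores
  te$net <- te$net + 100  # perturbing embeddings must not change anything
  p2 <- predict(m, te)$scores
  expect_identical(p1, p2)
})

test_that("cascade wiring trains and stays hierarchy-consistent", {
  fx <- tiny_trained()
  small <- subset_samples(fx$samples, fx$samples$ids[1:60])
  m <- train_model(build_model(model_spec(hierarchy_wiring = "cascade",
                                          class_layer_units = 4L),
                               fx$ds$termset, fx$ds$dag),
                   small, train_config(max_epochs = 2L, seed = 5L))
  expect_true(all(is.finite(m$history)))
  pred <- predict(m, subset_samples(fx$samples, fx$samples$ids[61:80]))
  expect_equal(nrow(check_hierarchy(pred, fx$ds$termset, fx$ds$dag)), 0L)
})

test_that("models persist and reload with identical predictions", {
  fx <- tiny_trained()
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(fx$model, f)
  back <- load_model(f)
  te <- subset_samples(fx$samples, fx$samples$ids[1:5])
  expect_identical(predict(back, te)$scores, predict(fx$model, te)$scores)
})

test_that("mismatched samples are rejected with a named mismatch", {
  fx <- tiny_trained()
  bad <- subset_samples(fx$samples, fx$samples$ids[1:3])
  bad$indices <- bad$indices[, 1:500]
  expect_error(predict(fx$model, bad), "seq_positions")
  bad2 <- subset_samples(fx$samples, fx$samples$ids[1:3])
  bad2$net <- bad2$net[, 1:10]
  expect_error(predict(fx$model, bad2), "net_dim")
})
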