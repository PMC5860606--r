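# random fixture helper shared by the metric-oracle tests
random_fixture <- function(np, nt, seed) {
  set.seed(seed)
  terms <- sprintf("T%02d", seq_len(nt))
  ids <- sprintf("p%02d", seq_len(np))
  S <- matrix(round(runif(np * nt), 2), np, nt, dimnames = list(ids, terms))
  Y <- matrix(rbinom(np * nt, 1, 0.4), np, nt, dimnames = list(ids, terms))
  # every protein gets at least one true term
  for (i in which(rowSums(Y) == 0)) Y[i, sample(nt, 1)] <- 1L
  truth <- lapply(ids, function(p) terms[Y[p, ] == 1])
  names(truth) <- ids
  list(pred = prediction_matrix(S, terms), S = S, Y = Y, truth = truth)
}

test_that("protein-centric Fmax handles perfect, empty and degenerate cases", {
  fx <- random_fixture(4, 5, 31)
  perfect <- prediction_matrix(fx$Y + 0, colnames(fx$Y))
  pf <- protein_fmax(perfect, fx$truth)
  expect_equal(pf$fmax, 1)
  expect_equal(pf$avgpr, 1)
  expect_equal(pf$avgrc, 1)
  expect_gt(pf$t_max, 0)

  zero <- prediction_matrix(fx$Y * 0, colnames(fx$Y))
  # at t = 0 everything is predicted; above 0 nothing: Fmax is the all-terms F
  pf0 <- protein_fmax(zero, fx$truth, thresholds = c(0.5, 1))
  expect_equal(pf0$fmax, 0)

  # Fmax reported with the harmonic-mean identity intact
  pf2 <- protein_fmax(fx$pred, fx$truth)
  expect_equal(pf2$fmax,
               2 * pf2$avgpr * pf2$avgrc / (pf2$avgpr + pf2$avgrc))
})

test_that("protein-centric Fmax equals the brute-force threshold oracle", {
  for (seed in 1:40) {
    np <- sample(2:10, 1); nt <- sample(2:8, 1)
    fx <- random_fixture(np, nt, seed + 500)
    grid <- sort(unique(c(0, as.vector(fx$S), 1)))
    expect_equal(protein_fmax(fx$pred, fx$truth, grid)$fmax,
                 fmax_oracle(fx$S, fx$Y, grid),
                 tolerance = 1e-12, info = seed)
  }
})

test_that("Fmax is invariant to strictly monotone score transforms", {
  fx <- random_fixture(6, 6, 77)
  grid1 <- sort(unique(as.vector(fx$S)))
  m1 <- protein_fmax(fx$pred, fx$truth, grid1)$fmax
  S2 <- fx$S^3  # strictly monotone on [0,1]
  grid2 <- sort(unique(as.vector(S2)))
  m2 <- protein_fmax(prediction_matrix(S2, fx$pred$terms), fx$truth, grid2)$fmax
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("term-centric AUC matches the all-pairs rank oracle", {
  fx <- random_fixture(8, 4, 32)
  expect_equal(term_auc(prediction_matrix(fx$Y + 0, fx$pred$terms),
                        fx$truth, fx$pred$terms[1]), 1)
  inv <- prediction_matrix(1 - fx$Y, fx$pred$terms)
  expect_equal(term_auc(inv, fx$truth, fx$pred$terms[1]), 0)

  for (seed in 1:40) {
    fx <- random_fixture(sample(3:10, 1), sample(2:8, 1), seed + 900)
    for (tm in fx$pred$terms) {
      expect_equal(term_auc(fx$pred, fx$truth, tm),
                   auc_pairs_oracle(fx$S[, tm], fx$Y[, tm]),
                   tolerance = 1e-12, info = paste(seed, tm))
    }
  }
})

test_that("term-centric Fmax matches the threshold-sweep oracle", {
  fx <- random_fixture(8, 4, 33)
  perfect <- prediction_matrix(fx$Y + 0, fx$pred$terms)
  expect_equal(term_fmax(perfect, fx$truth, fx$pred$terms[2]), 1)
  zero <- prediction_matrix(fx$Y * 0, fx$pred$terms)
  expect_equal(term_fmax(zero, fx$truth, fx$pred$terms[2],
                         thresholds = c(0.5, 1)), 0)

  for (seed in 1:30) {
    fx <- random_fixture(sample(3:10, 1), sample(2:8, 1), seed + 1300)
    grid <- sort(unique(c(0, as.vector(fx$S))))
    for (tm in fx$pred$terms)
      expect_equal(term_fmax(fx$pred, fx$truth, tm, grid),
                   term_fmax_oracle(fx$S[, tm], fx$Y[, tm], grid),
                   tolerance = 1e-12)
  }
})

test_that("global AUC micro-pools every (protein, term) pair", {
  fx <- random_fixture(5, 4, 34)
  perfect <- prediction_matrix(fx$Y + 0, fx$pred$terms)
  expect_equal(global_auc(perfect, fx$truth), 1)

  # single positive pair only -> undefined
  one <- prediction_matrix(matrix(0.7, 1, 1, dimnames = list("p", "T1")), "T1")
  expect_true(is.na(global_auc(one, list(p = "T1"))))

  for (seed in 1:30) {
    fx <- random_fixture(5, 4, seed + 1700)
    expect_equal(global_auc(fx$pred, fx$truth),
                 auc_pairs_oracle(as.vector(fx$S), as.vector(fx$Y)),
                 tolerance = 1e-12)
  }
})

test_that("MCC evaluates the closed form on pooled confusion counts", {
  fx <- random_fixture(4, 4, 35)
  perfect <- prediction_matrix(fx$Y + 0, fx$pred$terms)
  expect_equal(mcc_at(perfect, fx$truth, 0.5), 1)
  compl <- prediction_matrix(1 - fx$Y, fx$pred$terms)
  expect_equal(mcc_at(compl, fx$truth, 0.5), -1)

  # printed-fixture confusion counts: TP=3, FP=1, TN=4, FN=2
  S <- matrix(c(1, 1, 1, 1,   0, 0, 0, 0,  0, 0)[1:10], nrow = 2)
  Y <- rbind(c(1, 1, 1, 0, 1), c(0, 0, 0, 0, 1))
  # construct scores giving those counts: predictions = first 4 pairs
  S <- rbind(c(1, 1, 1, 1, 0), c(0, 0, 0, 0, 0))
  dimnames(S) <- dimnames(Y) <- list(c("p1", "p2"), sprintf("T%d", 1:5))
  truth <- list(p1 = colnames(Y)[Y["p1", ] == 1], p2 = colnames(Y)[Y["p2", ] == 1])
  pred <- prediction_matrix(S, colnames(S))
  expect_equal(mcc_at(pred, truth, 0.5),
               mcc_oracle(tp = 3, fp = 1, tn = 4, fn = 2))

  for (seed in 1:20) {
    fx <- random_fixture(5, 5, seed + 2100)
    t <- 0.5
    P <- fx$S >= t
    expect_equal(mcc_at(fx$pred, fx$truth, t),
                 mcc_oracle(sum(P & fx$Y == 1), sum(P & fx$Y == 0),
                            sum(!P & fx$Y == 0), sum(!P & fx$Y == 1)),
                 tolerance = 1e-12)
  }
})

test_that("the full report keeps metrics within range and consistent", {
  fx <- random_fixture(8, 6, 36)
  rep <- evaluate_predictions(fx$pred, fx$truth)
  expect_true(all(c(rep$fmax, rep$avgpr, rep$avgrc, rep$auc) >= 0))
  expect_true(all(c(rep$fmax, rep$avgpr, rep$avgrc, rep$auc) <= 1))
  expect_gte(rep$mcc, -1); expect_lte(rep$mcc, 1)
  expect_equal(rep$fmax, 2 * rep$avgpr * rep$avgrc / (rep$avgpr + rep$avgrc))
  expect_length(rep$term_auc, 6L)
})

test_that("grouped evaluation equals evaluation on each restriction", {
  fx <- random_fixture(9, 5, 37)
  grouping <- stats::setNames(rep(c("g1", "g2", "g3"), each = 3), fx$pred$ids)
  # single group covering everything reproduces the ungrouped report
  all1 <- evaluate_grouped(fx$pred, fx$truth,
                           stats::setNames(rep("g", 9), fx$pred$ids))
  expect_equal(all1$g$fmax, evaluate_predictions(fx$pred, fx$truth)$fmax)

  by <- evaluate_grouped(fx$pred, fx$truth, grouping)
  for (g in names(by)) {
    ids <- fx$pred$ids[grouping[fx$pred$ids] == g]
    sub <- prediction_matrix(fx$S[ids, , drop = FALSE], fx$pred$terms)
    expect_equal(by[[g]]$fmax, evaluate_predictions(sub, fx$truth[ids])$fmax)
    expect_equal(by[[g]]$auc, evaluate_predictions(sub, fx$truth[ids])$auc)
  }
})

test_that("prediction TSVs round-trip", {
  fx <- random_fixture(4, 3, 38)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(fx$pred, f, min_score = 0.000001)
  back <- read_predictions(f, terms = fx$pred$terms)
  keep <- fx$S >= 0.000001
  expect_equal(back$scores[fx$pred$ids, ][keep], fx$S[keep], tolerance = 1e-9)
})
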