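toy_scores <- c(0.9, 0.4, 0.6, 0.1)
toy_truth <- c(1, 1, 0, 0)

test_that("confusion counts match enumeration on the 4-cell toy", {
  expect_equal(confusion_counts(toy_scores, toy_truth, 0.5),
               c(TP = 1, FP = 1, FN = 1, TN = 1))
  # perfect classifier
  expect_equal(confusion_counts(toy_truth, toy_truth, 0.5),
               c(TP = 2, FP = 0, FN = 0, TN = 2))
  # threshold above every score predicts nothing positive
  expect_equal(confusion_counts(toy_scores, toy_truth, 2)[c("TP", "FP")],
               c(TP = 0, FP = 0))
  # -1 truth counts as class 0
  expect_equal(confusion_counts(c(0.9, 0.9), c(1, -1), 0.5),
               c(TP = 1, FP = 1, FN = 0, TN = 0))
  expect_error(confusion_counts(numeric(0), numeric(0), 0.5), "empty")
})

test_that("precision/recall/F follow the zero conventions", {
  expect_equal(prf(c(TP = 1, FP = 1, FN = 0)),
               c(precision = 0.5, recall = 1, f_score = 2 / 3))
  expect_equal(unname(prf(c(TP = 0, FP = 0, FN = 0))), c(0, 0, 0))
  # P = R implies F = P (harmonic mean identity)
  out <- prf(c(TP = 3, FP = 1, FN = 1))
  expect_equal(out[["f_score"]], out[["precision"]])
  expect_error(prf(c(TP = -1, FP = 0, FN = 0)), "non-negative")
})

test_that("rank AUC matches pair counting, handles ties, rejects one class", {
  expect_equal(roc_auc(toy_scores, toy_truth), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(roc_auc(toy_scores, rep(1, 4)), "positive and one negative")
  for (seed in 1:5) {
    set.seed(seed)
    sc <- round(runif(8), 1)               # provoke ties
    tr <- rbinom(8, 1, 0.5)
    if (sum(tr) %in% c(0, 8)) next
    expect_equal(roc_auc(sc, tr), oracle_auc(sc, tr))
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(3 * sc), tr), roc_auc(sc, tr))
  }
})

test_that("best-F threshold scan matches the exhaustive oracle", {
  # exhaustive scan of the 4-cell toy: t <= 0.4 predicts {0.9, 0.6, 0.4},
  # giving TP=2 FP=1 FN=0 -> F = 0.8, the maximum (frozen from the oracle)
  out <- best_f_threshold(toy_scores, toy_truth)
  expect_equal(out$report$f_score, 0.8)
  expect_equal(out$report$f_score, oracle_best_f(toy_scores, toy_truth))
  expect_gt(out$threshold, 0.1)
  expect_lte(out$threshold, 0.4)
  # perfectly separated scores reach F = 1
  expect_equal(best_f_threshold(c(.9, .8, .2, .1), c(1, 1, 0, 0))$report$f_score, 1)
  for (seed in 1:6) {
    set.seed(seed)
    sc <- round(runif(8), 1)
    tr <- rbinom(8, 1, 0.4)
    expect_equal(best_f_threshold(sc, tr)$report$f_score,
                 oracle_best_f(sc, tr))
  }
  # duplicating the top-scoring positive never lowers the best F
  base <- best_f_threshold(toy_scores, toy_truth)$report$f_score
  more <- best_f_threshold(c(toy_scores, 0.9), c(toy_truth, 1))$report$f_score
  expect_gte(more, base)
})

test_that("fold assignment partitions positives into near-equal folds", {
  s <- tiny_triple(seed = 17)
  folds <- cv_folds(s$assoc, 10, seed = 17)
  expect_identical(folds, cv_folds(s$assoc, 10, seed = 17))
  expect_setequal(as.integer(names(folds)), which(s$assoc == 1))
  expect_lte(diff(range(table(folds))), 1)
  expect_error(cv_folds(labeled_matrix(diag(2), c("a", "b"), c("x", "y")), 10),
               "n_folds")
})

test_that("cross_validate masks held-out cells and pools counts exactly", {
  s <- tiny_triple(seed = 18)
  enc <- encode(fit_autoencoder(build_autoencoder(
    fast_encoder(ncol(s$features), seed = 18)), s$features), s$features)
  cv <- cross_validate(s$assoc, s$side_effects, enc, top_k = 5, n_folds = 5,
                       seed = 18, keep_training = TRUE)
  for (fold in cv$folds) {
    # no-leakage: every held-out positive is 0 in its training matrix
    expect_true(all(fold$train_assoc[fold$held_out] == 0))
    # evaluation cells never intersect the cells the weights were fit on as 1
    expect_true(all(s$assoc[fold$held_out] == 1))
  }
  for (mode in c("adaptive", "uniform")) {
    rep <- cv[[mode]]
    pooled <- Reduce(`+`, rep$fold_counts)
    expect_equal(pooled[c("TP", "FP", "FN", "TN")],
                 unlist(rep[c("TP", "FP", "FN", "TN")]))
    expect_equal(sum(pooled), 5 * sum(s$assoc != 1) + sum(s$assoc == 1))
    expect_true(rep$auc >= 0 && rep$auc <= 1)
  }
})

test_that("threshold sweep counts per-disease top-n recoveries", {
  truth <- labeled_matrix(rbind(d1 = c(1, 0), d2 = c(0, 0), d3 = c(0, 1)),
                          col_labels = c("e1", "e2"))
  scores <- labeled_matrix(rbind(d1 = c(.9, .2), d2 = c(.5, .3),
                                 d3 = c(.1, .8)),
                           col_labels = c("e1", "e2"))
  out <- threshold_sweep_counts(scores, truth, top_n = c(0, 1, 3))
  expect_equal(out$count, c(0, 2, 2))        # both positives ranked first
  expect_equal(out$fraction, c(0, 1, 1))
  s <- tiny_triple(seed = 19)
  p <- simple_average_fuse(predict_sources(
    mark_side_effects(s$assoc, s$side_effects),
    s$features, s$side_effects, 5))
  full <- threshold_sweep_counts(p, s$assoc, top_n = nrow(s$assoc))
  expect_equal(full$fraction, 1)             # top_n = n_drugs recovers all
})
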