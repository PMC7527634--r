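test_that("confusion counts match a naive four-way tally", {
  c0 <- confusion(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(c0$pos_as_neg, 0)
  expect_equal(c0$neg_as_pos, 0)
  c1 <- confusion(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(c1$pos_as_neg, c1$h_pos)
  expect_equal(c1$neg_as_pos, c1$h_neg)
  set.seed(71)
  for (rep in 1:20) {
    t <- sample(0:1, 30, replace = TRUE)
    p <- sample(0:1, 30, replace = TRUE)
    cc <- confusion(t, p)
    expect_equal(cc$h_pos, sum(t == 0))
    expect_equal(cc$h_neg, sum(t == 1))
    expect_equal(cc$pos_as_neg, sum(t == 0 & p == 1))
    expect_equal(cc$neg_as_pos, sum(t == 1 & p == 0))
  }
  expect_error(confusion(c(0, 1), c(0)), "equal length")
  # label-name and 0/1 encodings agree
  expect_equal(confusion(c("hotspot", "coldspot"), c("coldspot", "coldspot")),
               confusion(c(0, 1), c(1, 1)))
})

test_that("hotspot-centric metrics equal the standard confusion formulas", {
  m <- compute_metrics(confusion(rep(c(0, 1), each = 10), rep(c(0, 1), each = 10)))
  expect_equal(unlist(m[c("acc", "sn", "sp", "mcc")]),
               c(acc = 1, sn = 1, sp = 1, mcc = 1))
  # frozen worked example: TP=3, FN=1, TN=4, FP=2
  m2 <- compute_metrics(confusion(c(rep(0, 4), rep(1, 6)),
                                  c(0, 0, 0, 1, 0, 0, 1, 1, 1, 1)))
  expect_equal(m2$acc, 0.7)
  expect_equal(m2$sn, 0.75)
  expect_equal(m2$sp, 2 / 3)
  expect_equal(m2$mcc, 10 / sqrt(600), tolerance = 1e-12)
  # spot agreement with the standard formulation on random tables
  set.seed(81)
  for (rep in 1:50) {
    hp <- sample(1:15, 1); hn <- sample(1:15, 1)
    fn <- sample(0:hp, 1); fp <- sample(0:hn, 1)
    cc <- structure(list(h_pos = hp, h_neg = hn, pos_as_neg = fn,
                         neg_as_pos = fp), class = "confusion_counts")
    m <- compute_metrics(cc)
    tp <- hp - fn; tn <- hn - fp
    expect_equal(m$acc, (tp + tn) / (hp + hn))
    expect_equal(m$sn, tp / hp)
    expect_equal(m$sp, tn / hn)
    expect_equal(m$mcc, standard_mcc(tp, fp, tn, fn), tolerance = 1e-12)
  }
})

test_that("degenerate confusion tables never yield silent NaN", {
  all_pos_pred <- compute_metrics(confusion(c(0, 0, 1, 1), c(0, 0, 0, 0)))
  expect_equal(all_pos_pred$mcc, 0)  # zero denominator convention
  expect_false(any(is.nan(unlist(all_pos_pred[c("acc", "sn", "sp", "mcc")]))))
  expect_warning(one_class <- compute_metrics(confusion(c(0, 0), c(0, 1))),
                 "SP undefined")
  expect_true(is.na(one_class$sp))
  expect_equal(one_class$sn, 0.5)
})

test_that("ROC sweeps thresholds from (0,0) to (1,1) and AUC matches U", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.2, 0.1), c(0, 0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$fpr) >= 0))

  set.seed(91)
  for (rep in 1:20) {
    n <- 40
    t <- sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(t)) < 2) next
    s <- round(runif(n), 1)  # force ties
    r <- roc_auc(s, t)
    pos <- s[t == 0]; neg <- s[t == 1]
    u <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(r$auc, u, tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(3 * s), t)$auc, r$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.1, 0.2), c(0, 0)), "both classes")
})

test_that("random scores give chance-level AUC", {
  set.seed(101)
  t <- rep(0:1, each = 1000)
  r <- roc_auc(runif(2000), t)
  expect_lt(abs(r$auc - 0.5), 0.05)
})

test_that("stratified folds balance classes within one sample", {
  y <- rep(c(0, 1), c(100, 100))
  f <- make_folds(y, 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  for (k in 1:10) {
    expect_equal(sum(f == k & y == 0), 10)
    expect_equal(sum(f == k & y == 1), 10)
  }
  expect_identical(f, make_folds(y, 10, seed = 3))
  expect_false(identical(f, make_folds(y, 10, seed = 4)))
  expect_error(make_folds(rep(c(0, 1), c(5, 100)), 10), "smaller k")
})

test_that("cross-validation pools held-out predictions over stratified folds", {
  d <- tiny_dataset(n_per = 20, L = 100, effect = 0.6, seed = 12)
  p <- pipeline_spec(group = "G4",
                     selection_sizes = c(G = 5, R = 12, P = 66, H = 425),
                     rfe_step = 0.5,
                     classifier = list(kind = "knn", params = list(k = 3)))
  rep5 <- cross_validate(d, p, k = 5, seed = 2)
  expect_s3_class(rep5, "cv_report")
  expect_equal(nrow(rep5$per_fold), 5)
  expect_equal(rep5$hybrid$dim, 83)
  # folds partition the samples, stratified
  expect_equal(sort(unique(rep5$folds)), 1:5)
  for (k in 1:5)
    expect_equal(sum(rep5$folds == k & d$label == "hotspot"), 4)
  # pooled confusion equals the sum of per-fold confusions
  per_fold_err <- vapply(1:5, function(k) {
    te <- rep5$predictions[rep5$predictions$fold == k, ]
    sum(te$truth != te$pred)
  }, numeric(1))
  expect_equal(sum(per_fold_err),
               rep5$pooled$counts$pos_as_neg + rep5$pooled$counts$neg_as_pos)
  # strong planted signal is learnable even by 3-NN
  expect_gt(rep5$pooled$acc, 0.8)
  # fold assignment reproducible; same seed -> same report
  rep5b <- cross_validate(d, p, k = 5, seed = 2)
  expect_identical(rep5$predictions, rep5b$predictions)
  expect_error(cross_validate(d, p, k = 25, seed = 1), "smaller k")
})

test_that("whole-dataset selection ranks once and changes the protocol only", {
  d <- tiny_dataset(n_per = 12, L = 90, effect = 0.6, seed = 13)
  p <- pipeline_spec(group = "G2", rfe_step = 0.5,
                     classifier = list(kind = "knn", params = list(k = 3)))
  r1 <- cross_validate(d, p, k = 3, seed = 1,
                       leakage_mode = "whole-dataset-selection")
  expect_equal(r1$leakage_mode, "whole-dataset-selection")
  expect_equal(r1$hybrid$dim, 78)
  expect_true(r1$pooled$acc >= 0 && r1$pooled$acc <= 1)
})

test_that("unlabeled records are rejected for cross-validation", {
  d <- tiny_dataset(n_per = 12, L = 60, seed = 14)
  d$label[1] <- NA
  p <- pipeline_spec(group = "G4", classifier = list(kind = "knn"))
  expect_error(cross_validate(d, p, k = 3), "labeled")
})

test_that("grid search scores every cell and applies the tie rule", {
  d <- tiny_dataset(n_per = 10, L = 80, effect = 0.7, seed = 15)
  p <- pipeline_spec(group = "G4", rfe_step = 0.5,
                     classifier = list(kind = "dnn", hidden_widths = c(4),
                                       iterations = 40))
  g <- grid_search(d, rates = c(0.1, 0.3), activations = c("tanh", "relu"),
                   p, k = 2, seed = 3)
  expect_equal(nrow(g$grid), 4)
  expect_equal(g$best$acc, max(g$grid$acc))
  # ties break to the lowest learning rate, then first-listed activation
  tied <- g$grid[g$grid$acc == max(g$grid$acc), ]
  expect_equal(g$best$learning_rate, min(tied$learning_rate))
  expect_error(grid_search(d, numeric(0), "tanh", p), "empty grid")
  # single cell is trivially best
  g1 <- grid_search(d, 0.1, "tanh", p, k = 2, seed = 3)
  expect_equal(nrow(g1$grid), 1)
  expect_equal(g1$best$learning_rate, 0.1)
})
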