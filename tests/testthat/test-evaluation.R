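# Independent brute-force oracle for the four confusion-matrix metrics,
# written directly from their definitions.
oracle_metrics <- function(tp, tn, fp, fn) {
  list(
    Sn = tp / (tp + fn),
    Sp = tn / (tn + fp),
    Acc = (tp + tn) / (tp + tn + fp + fn),
    MCC = (tp * tn - fp * fn) /
      sqrt(tp + fp) / sqrt(tp + fn) / sqrt(tn + fp) / sqrt(tn + fn)
  )
}

# Brute-force AUC: fraction of (positive, negative) pairs where the positive
# outscores the negative, ties counting one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("confusion counts partition the examples", {
  cnt <- confusion(rep(c(1, 0), c(10, 10)), rep(c(1, 0), c(10, 10)))
  expect_equal(unclass(cnt)[c("TP", "TN", "FP", "FN")],
               c(TP = 10L, TN = 10L, FP = 0L, FN = 0L))
  cnt <- confusion(rep(1, 20), rep(c(1, 0), c(10, 10)))
  expect_equal(unclass(cnt)[c("TP", "FP")], c(TP = 10L, FP = 10L))
  set.seed(1)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    cnt <- confusion(sample(0:1, n, TRUE), sample(0:1, n, TRUE))
    expect_equal(sum(cnt), n)
  }
  expect_error(confusion(1, c(1, 0)), "equal length")
})

test_that("metrics evaluate the four formulas exactly", {
  m <- metrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unlist(m[c("Sn", "Sp", "Acc", "MCC")]),
               c(Sn = 1, Sp = 1, Acc = 1, MCC = 1))
  m <- metrics(c(TP = 5, TN = 5, FP = 5, FN = 5))
  expect_equal(m$MCC, 0)
  expect_equal(m$Acc, 0.5)
  expect_false(m$mcc_undefined)
  m <- metrics(c(TP = 90, TN = 90, FP = 10, FN = 10))
  expect_equal(unlist(m[c("Sn", "Sp", "Acc", "MCC")]),
               c(Sn = 0.9, Sp = 0.9, Acc = 0.9, MCC = 0.8))
})

test_that("degenerate confusion matrices are flagged, not silently zeroed", {
  m <- metrics(c(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_true(is.na(m$Sn))
  expect_equal(m$Sp, 1)
  expect_true(m$mcc_undefined)
  expect_equal(m$MCC, 0)
  expect_error(metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("MCC antisymmetry and the accuracy identity hold", {
  set.seed(7)
  for (i in 1:50) {
    cnt <- c(TP = sample(0:40, 1), TN = sample(0:40, 1),
             FP = sample(0:40, 1), FN = sample(0:40, 1))
    if (sum(cnt) == 0) next
    m <- metrics(cnt)
    # inverting all predictions swaps TP<->FN and TN<->FP: negates MCC
    inv <- metrics(c(TP = cnt[["FN"]], TN = cnt[["FP"]],
                     FP = cnt[["TN"]], FN = cnt[["TP"]]))
    expect_equal(inv$MCC, -m$MCC, tolerance = 1e-12)
    # swapping classes (TP<->TN, FP<->FN) leaves MCC unchanged
    sw <- metrics(c(TP = cnt[["TN"]], TN = cnt[["TP"]],
                    FP = cnt[["FN"]], FN = cnt[["FP"]]))
    expect_equal(sw$MCC, m$MCC, tolerance = 1e-12)
    # Acc == (Sn*P + Sp*N) / (P + N)
    P <- cnt[["TP"]] + cnt[["FN"]]; N <- cnt[["TN"]] + cnt[["FP"]]
    if (P > 0 && N > 0) {
      expect_equal(m$Acc, (m$Sn * P + m$Sp * N) / (P + N), tolerance = 1e-12)
    }
  }
})

test_that("positive-only TP/FN bookkeeping conserves class prevalence", {
  actual <- rep(c("S24", "S70"), c(30, 10))
  predicted <- c(rep("S24", 24), rep("S70", 6), rep("S70", 10))
  expect_equal(positive_only_counts(predicted, actual, "S24"),
               c(TP = 24L, FN = 6L))
  expect_equal(positive_only_counts(predicted, actual, "S38"),
               c(TP = 0L, FN = 0L))
  set.seed(3)
  pred <- sample(sigma_labels(), 40, TRUE)
  cnt <- positive_only_counts(pred, actual, "S24")
  expect_equal(sum(cnt), 30)
  expect_error(positive_only_counts(pred, c(actual[-1], "NON_PROMOTER"),
                                    "S24"), "promoter-only")
})

test_that("stratified folds partition each class near-evenly", {
  y <- rep(c(1, 0), c(50, 50))
  folds <- kfold_split(y, k = 5, seed = 1)
  expect_equal(sort(unique(folds)), 1:5)
  expect_true(all(table(folds) == 20))
  expect_true(all(table(folds, y) == 10))
  expect_identical(folds, kfold_split(y, k = 5, seed = 1))
  expect_false(identical(folds, kfold_split(y, k = 5, seed = 2)))
  expect_error(kfold_split(rep(c("a", "b"), c(3, 60)), k = 5), "fewer than")
})

test_that("ROC/AUC equals pairwise concordance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$tpr) >= 0))
    expect_true(all(diff(r$fpr) >= 0))
    expect_true(r$auc >= 0 && r$auc <= 1)
  }
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("metrics agree with the brute-force oracle on random counts", {
  set.seed(13)
  for (i in 1:200) {
    cnt <- c(TP = sample(1:60, 1), TN = sample(1:60, 1),
             FP = sample(1:60, 1), FN = sample(1:60, 1))
    m <- metrics(cnt)
    o <- oracle_metrics(cnt[["TP"]], cnt[["TN"]], cnt[["FP"]], cnt[["FN"]])
    for (nm in names(o)) expect_equal(m[[nm]], o[[nm]], tolerance = 1e-12)
  }
})

test_that("cross-validation returns k folds and learns separable data", {
  ds <- promn_dataset(n_each = 60, mutation_rate = 0)
  y <- as.numeric(ds$label != "NON_PROMOTER")
  cv <- cross_validate(ds$seq, y, tiny_arch(), tiny_train(epochs = 40L),
                       k = 5, seed = 1)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(cv$per_fold$fold, 1:5)
  expect_gt(cv$mean[["Acc"]], 0.9)
  expect_gt(cv$mean[["AUC"]], 0.95)
})

test_that("the hyper-parameter grid enumerates the documented space", {
  g <- hyper_grid()
  expect_equal(nrow(g), 5 * 5 * 2 * 7 * 4)  # 1400
  expect_setequal(unique(g$conv_filters), c(8, 16, 32, 64, 128))
  expect_setequal(unique(g$kernel1), c(3, 5, 7, 9, 11))
  expect_setequal(unique(g$pool), c(2, 4))
  expect_equal(sort(unique(g$dropout1)), seq(0.15, 0.45, by = 0.05))
  expect_setequal(unique(g$dense_units), c(8, 16, 32, 64))
  expect_true(all(g$kernel1 == g$kernel2))
  u <- hyper_grid(tied = FALSE)
  expect_equal(nrow(u), 5 * 5 * 5 * 2 * 7 * 7 * 4)
  expect_error(grid_search(data.frame(), "ACGT", 1), "empty")
})

test_that("grid search ranks configurations by cross-validated MCC", {
  ds <- promn_dataset(n_each = 20, mutation_rate = 0)
  y <- as.numeric(ds$label != "NON_PROMOTER")
  small_grid <- hyper_grid(conv_filters = 4L, kernel_sizes = c(3L, 5L),
                           pool_sizes = 2L, dropout_ratios = 0.2,
                           dense_units = 4L)
  expect_equal(nrow(small_grid), 2)
  ranked <- grid_search(small_grid, ds$seq, y, tiny_train(epochs = 3L),
                        k = 2, seed = 1)
  expect_equal(nrow(ranked), 2)
  expect_true(all(diff(ranked$mean_mcc) <= 0))
  one <- grid_search(small_grid, ds$seq, y, tiny_train(epochs = 3L),
                     k = 2, budget = 1, seed = 1)
  expect_equal(nrow(one), 1)
})
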