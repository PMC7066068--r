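test_that("LOOCV on well-separated Gaussian classes is error-free", {
  d <- separated_gaussians(n_per_class = 20, delta = 6, seed = 42)
  pred <- cross_validated_predictions(d$matrix, d$labels)
  expect_identical(as.character(pred), unname(d$labels))
  cm <- confusion(pred, d$labels, positive = "tumor")
  expect_equal(mcc(cm), 1)
})

test_that("LOOCV is deterministic and predicts each sample exactly once", {
  d <- separated_gaussians(n_per_class = 10, seed = 5)
  p1 <- cross_validated_predictions(d$matrix, d$labels)
  p2 <- cross_validated_predictions(d$matrix, d$labels)
  expect_identical(p1, p2)
  expect_identical(length(p1), ncol(d$matrix))
  expect_identical(names(p1), colnames(d$matrix))
})

test_that("permuted labels drop accuracy to around the majority-class rate", {
  d <- separated_gaussians(n_per_class = 20, delta = 6, seed = 42)
  set.seed(77)
  acc <- replicate(50, {
    perm <- stats::setNames(sample(unname(d$labels)), names(d$labels))
    pred <- cross_validated_predictions(d$matrix, perm,
                                        cv = cv_scheme("stratified_kfold",
                                                       k = 5, seed = 1))
    mean(as.character(pred) == unname(perm))
  })
  # balanced classes: chance accuracy 0.5; cross-validated estimates are
  # pessimistic under the null, so allow a generous band below and a
  # binomial-noise band above
  expect_lt(mean(acc), 0.55)
  expect_gt(mean(acc), 0.2)
})

test_that("a fold that loses a class raises an advisory error", {
  d <- separated_gaussians(n_per_class = 3, seed = 9)
  # keep a single periphery cell: LOOCV holding it out leaves one class
  keep <- c(1:3, 4)
  expect_error(
    cross_validated_predictions(d$matrix[, keep], d$labels[keep]),
    "stratified_kfold|more data")
})

test_that("confusion counts the four cells and conserves N", {
  pred <- c("t", "t", "t", "p", "p")
  act <- c("t", "t", "t", "p", "p")
  cm <- confusion(pred, act, positive = "t")
  expect_identical(c(cm$TP, cm$TN, cm$FP, cm$FN), c(3L, 2L, 0L, 0L))
  cm2 <- confusion(rep("t", 5), act, positive = "t")
  expect_identical(c(cm2$TP, cm2$FP, cm2$TN, cm2$FN), c(3L, 2L, 0L, 0L))
  expect_identical(cm2$TP + cm2$FP + cm2$TN + cm2$FN, 5L)
  expect_error(confusion(c("t", "x", "p"), act[1:3], positive = "t"),
               "outside")
})

test_that("published-scale confusion matrix reproduces the printed metrics", {
  # 2343 tumor cells split 2220/123, 1246 periphery cells split 181/1065
  cm <- confusion_counts(TP = 2220, FN = 123, FP = 181, TN = 1065)
  expect_identical(cm$TP + cm$FN, 2343)
  expect_identical(cm$TN + cm$FP, 1246)
  expect_equal(round(mcc(cm), 3), 0.812)
  expect_equal(round(sensitivity(cm), 3), 0.948)
  expect_equal(round(specificity(cm), 3), 0.855)
  expect_equal(round(accuracy(cm), 3), 0.915)
})

test_that("MCC hits its closed-form values and degenerate convention", {
  expect_equal(mcc(confusion_counts(TP = 10, TN = 10, FP = 0, FN = 0)), 1)
  expect_equal(mcc(confusion_counts(TP = 5, TN = 5, FP = 5, FN = 5)), 0)
  expect_equal(mcc(confusion_counts(TP = 0, TN = 5, FP = 0, FN = 5)), 0)  # 0/0
})

test_that("MCC symmetry, bounds and the accuracy decomposition hold", {
  set.seed(88)
  for (i in 1:200) {
    cts <- sample(0:40, 4, replace = TRUE)
    cm <- confusion_counts(TP = cts[1], FP = cts[2], TN = cts[3], FN = cts[4])
    v <- mcc(cm)
    expect_lte(abs(v), 1 + 1e-12)
    # swapping TP<->TN and FP<->FN leaves MCC unchanged
    expect_equal(v, mcc(confusion_counts(TP = cts[3], FP = cts[4],
                                         TN = cts[1], FN = cts[2])),
                 tolerance = 1e-12)
    # negating predictions negates MCC (when no margin is empty)
    flip <- confusion_counts(TP = cts[4], FP = cts[3], TN = cts[2], FN = cts[1])
    den_ok <- all(c(cm$TP + cm$FP, cm$TP + cm$FN, cm$TN + cm$FP,
                    cm$TN + cm$FN) > 0)
    if (den_ok) expect_equal(mcc(flip), -v, tolerance = 1e-12)
    P <- cm$TP + cm$FN; Neg <- cm$TN + cm$FP
    if (P > 0 && Neg > 0) {
      expect_equal(accuracy(cm),
                   (sensitivity(cm) * P + specificity(cm) * Neg) / (P + Neg),
                   tolerance = 1e-12)
    }
  }
  expect_error(sensitivity(confusion_counts(0, 3, 2, 0)), "positives")
  expect_error(specificity(confusion_counts(3, 0, 0, 2)), "negatives")
})

test_that("stratified k-fold covers every sample once and respects its seed", {
  d <- separated_gaussians(n_per_class = 15, seed = 3)
  cv <- cv_scheme("stratified_kfold", k = 5, seed = 10)
  p1 <- cross_validated_predictions(d$matrix, d$labels, cv = cv)
  p2 <- cross_validated_predictions(d$matrix, d$labels, cv = cv)
  expect_identical(p1, p2)
  expect_identical(length(p1), 30L)
})
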