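test_that("confusion counts from label vectors", {
  cm <- confusion_from_labels(c("engaged", "engaged", "distracted"),
                              c("engaged", "engaged", "distracted"))
  expect_equal(c(cm$TP, cm$TN, cm$FP, cm$FN), c(2, 1, 0, 0))
  cm2 <- confusion_from_labels("engaged", "distracted")
  expect_equal(cm2$FP, 1)
  expect_error(confusion_from_labels("engaged", c("engaged", "engaged")),
               "equal length")
  expect_error(confusion_from_labels("yes", "engaged"), "labels")

  # seeded random vectors against a pairwise enumeration oracle
  set.seed(51)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    pred <- sample(c("engaged", "distracted"), n, replace = TRUE)
    truth <- sample(c("engaged", "distracted"), n, replace = TRUE)
    cm <- confusion_from_labels(pred, truth)
    counts <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    for (k in seq_len(n)) {
      key <- if (truth[k] == "engaged") {
        if (pred[k] == "engaged") "TP" else "FN"
      } else {
        if (pred[k] == "engaged") "FP" else "TN"
      }
      counts[key] <- counts[key] + 1
    }
    expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]), counts)
  }
})

test_that("confusion matrix is reconstructed from published marginals", {
  cm <- confusion_from_marginals(989, 941, 952, 3)
  expect_equal(c(cm$TP, cm$FP, cm$TN, cm$FN), c(938, 14, 34, 3))
  cm2 <- confusion_from_marginals(4, 2, 2, 0)
  expect_equal(c(cm2$TP, cm2$FP, cm2$TN, cm2$FN), c(2, 0, 2, 0))
  # more false negatives than truly engaged trials, or counts that force a
  # negative cell, cannot come from any real matrix
  expect_error(confusion_from_marginals(4, 3, 1, 4), "inconsistent")
  expect_error(confusion_from_marginals(5, 2, 5, 2), "inconsistent")
  # round trip: marginals of any valid matrix reproduce it
  set.seed(52)
  for (i in 1:20) {
    cm0 <- confusion_matrix(TP = rpois(1, 50), TN = rpois(1, 10),
                            FP = rpois(1, 5), FN = rpois(1, 5) + 1)
    total <- cm0$TP + cm0$TN + cm0$FP + cm0$FN
    back <- confusion_from_marginals(total, cm0$TP + cm0$FN,
                                     cm0$TP + cm0$FP, cm0$FN)
    expect_equal(unclass(back), unclass(cm0))
  }
})

test_that("metric formulas reproduce the published worked example", {
  m <- compute_metrics(confusion_from_marginals(989, 941, 952, 3))
  expect_equal(m$rounded$accuracy, 98.3)
  expect_equal(m$rounded$precision, 98.5)
  expect_equal(m$rounded$sensitivity, 99.7)
  expect_equal(m$rounded$specificity, 70.8)
  expect_equal(m$rounded$f1, 99.1)
  expect_equal(m$rounded$mcc, 0.80)
})

test_that("degenerate confusion matrices follow the stated conventions", {
  perfect <- compute_metrics(confusion_matrix(10, 10, 0, 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "sensitivity",
                                "specificity", "f1")], use.names = FALSE),
               rep(100, 5))
  expect_equal(perfect$mcc, 1)

  # total disagreement: all marginals positive, so MCC is mathematically -1
  worst <- compute_metrics(confusion_matrix(0, 0, 5, 5))
  expect_equal(worst$accuracy, 0)
  expect_equal(worst$mcc, -1)

  # all-negative predictions: precision undefined, MCC 0 by convention
  allneg <- compute_metrics(confusion_matrix(0, 5, 0, 5))
  expect_true(is.na(allneg$precision))
  expect_equal(allneg$mcc, 0)
  expect_error(confusion_matrix(-1, 0, 0, 2), "non-negative")
  expect_error(confusion_matrix(0, 0, 0, 0), "at least one")
})

test_that("metrics agree with independent textbook formulas", {
  set.seed(53)
  for (i in 1:250) {
    cnt <- rpois(4, sample(c(2, 20, 200), 1))
    if (sum(cnt) == 0) cnt[1] <- 1
    m <- compute_metrics(confusion_matrix(cnt[1], cnt[2], cnt[3], cnt[4]))
    o <- metrics_oracle(cnt[1], cnt[2], cnt[3], cnt[4])
    for (f in names(o)) expect_equal(m[[f]], o[[f]], tolerance = 1e-12)
  }
})

test_that("F1 equals its 2TP/(2TP+FP+FN) algebraic form and MCC behaves", {
  set.seed(54)
  for (i in 1:100) {
    cnt <- rpois(4, 20) + c(1, 1, 0, 0)
    cm <- confusion_matrix(cnt[1], cnt[2], cnt[3], cnt[4])
    m <- compute_metrics(cm)
    expect_equal(m$f1, 100 * 2 * cm$TP / (2 * cm$TP + cm$FP + cm$FN),
                 tolerance = 1e-12)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    # swapping predicted labels (TP<->FN, FP<->TN) negates MCC
    sw <- compute_metrics(confusion_matrix(cm$FN, cm$FP, cm$TN, cm$TP))
    expect_equal(sw$mcc, -m$mcc, tolerance = 1e-12)
  }
  expect_equal(compute_metrics(confusion_matrix(7, 9, 0, 0))$mcc, 1)
})

test_that("blur velocity follows the kernel-size model", {
  expect_equal(blur_velocity(2, 60, 42, 1920), 2.625)
  expect_equal(round(blur_velocity(2, 60, 42, 1920)), 3)
  expect_equal(blur_velocity(6, 60, 42, 1920), 7.875)
  expect_equal(round(blur_velocity(6, 60, 42, 1920)), 8)
  expect_equal(blur_velocity(2, 120, 42, 1920),
               2 * blur_velocity(2, 60, 42, 1920))
  expect_error(blur_velocity(0, 60, 42, 1920), "positive")
})
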