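test_that("binarize thresholds with >= and validates its inputs", {
  expect_equal(binarize(matrix(0, 3, 3)), matrix(FALSE, 3, 3))
  expect_equal(binarize(matrix(1, 3, 3)), matrix(TRUE, 3, 3))
  # ties at the threshold are positive
  m <- matrix(c(0.49, 0.51, 0.50, 0.0), 2, 2)
  expect_equal(binarize(m, 0.5),
               matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_error(binarize(m, 0), "threshold")
  expect_error(binarize(m, 1), "threshold")
  expect_error(binarize(matrix(c(0.2, 1.2, 0, 0), 2, 2)), "\\[0, 1\\]")
})

test_that("confusion counts match hand-enumerated cases", {
  id <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE), 2, 3)
  cc <- confusion(id, id)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 3L, fp = 0L, fn = 0L, tn = 3L))

  empty_pred <- confusion(matrix(FALSE, 2, 3), id)
  expect_equal(empty_pred$tp, 0L)
  expect_equal(empty_pred$fn, 3L)

  # 4x4, pred 3 positives, truth 2, overlap 2
  pred <- matrix(FALSE, 4, 4); pred[c(1, 2, 3)] <- TRUE
  truth <- matrix(FALSE, 4, 4); truth[c(1, 2)] <- TRUE
  cc <- confusion(pred, truth)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 1L, fn = 0L, tn = 13L))

  expect_error(confusion(matrix(TRUE, 2, 2), matrix(TRUE, 2, 3)), "shapes differ")
})

test_that("metrics_from_counts evaluates the formulas and conventions", {
  m <- metrics_from_counts(confusion_counts(tp = 2, fp = 1, tn = 13, fn = 0))
  expect_equal(m, c(iou = 2 / 3, acc = 15 / 16, re = 1, pr = 2 / 3, f1 = 0.8))

  both_empty <- metrics_from_counts(confusion_counts(0, 0, 16, 0))
  expect_equal(unname(both_empty), rep(1, 5))

  disagree <- metrics_from_counts(confusion_counts(tp = 0, fp = 5, tn = 6, fn = 5))
  expect_equal(disagree[["iou"]], 0)
  expect_equal(disagree[["pr"]], 0)
  expect_equal(disagree[["re"]], 0)
  expect_equal(disagree[["f1"]], 0)

  expect_error(metrics_from_counts(confusion_counts(0, 0, 0, 0)), "zero")
  expect_error(confusion_counts(-1, 0, 1, 0), "non-negative")
})

test_that("evaluate_mask_set pools micro counts and per-image means", {
  pred <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  truth <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  single <- metrics_from_counts(confusion(pred, truth))
  expect_equal(evaluate_mask_set(list(list(pred, truth))), single)
  expect_equal(evaluate_mask_set(list(list(pred, truth)),
                                 pooling = "per_image_mean"), single)
  # duplication invariance
  twice <- list(list(pred, truth), list(pred, truth))
  expect_equal(evaluate_mask_set(twice), single)
  expect_equal(evaluate_mask_set(twice, pooling = "per_image_mean"), single)

  # summed-count oracle: (tp=1,fp=1,fn=0,tn=2) + (tp=3,fp=0,fn=1,tn=0)
  a_pred <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  a_truth <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  b_pred <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  b_truth <- matrix(TRUE, 2, 2)
  micro <- evaluate_mask_set(list(list(a_pred, a_truth), list(b_pred, b_truth)))
  expect_equal(micro[["iou"]], 4 / 6)

  # probability maps are binarized on the fly
  expect_equal(evaluate_mask_set(list(list(matrix(0.7, 2, 2), matrix(TRUE, 2, 2)))),
               c(iou = 1, acc = 1, re = 1, pr = 1, f1 = 1))
  expect_error(evaluate_mask_set(list()), "non-empty")
})

test_that("metric engine agrees with the brute-force pixel oracle", {
  set.seed(42)
  for (i in 1:200) {
    h <- sample(1:12, 1); w <- sample(1:12, 1)
    pred <- random_mask(h, w, runif(1))
    truth <- random_mask(h, w, runif(1))
    cc <- confusion(pred, truth)
    oracle <- brute_confusion(pred, truth)
    expect_identical(unclass(cc)[c("tp", "fp", "tn", "fn")],
                     oracle[c("tp", "fp", "tn", "fn")])
    m <- metrics_from_counts(cc)
    expect_equal(m, brute_metrics(oracle$tp, oracle$fp, oracle$tn, oracle$fn),
                 tolerance = 1e-15)
    if (cc$tp + cc$fp + cc$fn > 0) {
      expect_lte(m[["iou"]], m[["pr"]] + 1e-15)
      expect_lte(m[["iou"]], m[["re"]] + 1e-15)
      expect_equal(m[["iou"]], m[["f1"]] / (2 - m[["f1"]]), tolerance = 1e-12)
    }
  }
})

test_that("confusion respects complement symmetry and pixel permutation", {
  set.seed(7)
  for (i in 1:25) {
    pred <- random_mask(6, 7); truth <- random_mask(6, 7)
    cc <- confusion(pred, truth)
    flipped <- confusion(!pred, !truth)
    expect_equal(flipped$tp, cc$tn)
    expect_equal(flipped$tn, cc$tp)
    expect_equal(flipped$fp, cc$fn)
    expect_equal(flipped$fn, cc$fp)

    perm <- sample(length(pred))
    pp <- matrix(pred[perm], 6, 7); tt <- matrix(truth[perm], 6, 7)
    expect_equal(metrics_from_counts(confusion(pp, tt)),
                 metrics_from_counts(cc))
  }
})
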