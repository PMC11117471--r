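test_that("detection matching counts the confusion table", {
  gts <- dplyr::bind_rows(boxes(0, 0, 10, 10), boxes(30, 30, 42, 42))
  perfect <- dplyr::mutate(gts, score = c(0.9, 0.8))
  cc <- match_detections(perfect, gts, 0.5)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(2, 0, 0))

  none <- match_detections(boxes(), gts, 0.5)
  expect_equal(c(none$tp, none$fp, none$fn), c(0, 0, 2))

  # one det overlaps one GT at IoU 0.6, the other det is far away
  dets <- dplyr::bind_rows(boxes(0, 2, 10, 12, score = 0.9),  # IoU 80/120 = 2/3
                           boxes(70, 70, 80, 80, score = 0.8))
  expect_equal(box_iou(dets[1, ], gts[1, ], drop = TRUE), 2 / 3)
  cc2 <- match_detections(dets, gts, 0.5)
  expect_equal(c(cc2$tp, cc2$fp, cc2$fn), c(1, 1, 1))

  with_tn <- match_detections(dets, gts, 0.5, negatives_evaluated = 10)
  expect_equal(with_tn$tn, 9)
  expect_error(match_detections(dets, gts, 0.5, negatives_evaluated = 0),
               "inconsistent accounting")
  # matching is one-to-one: two dets cannot claim the same ground truth
  dup <- dplyr::bind_rows(boxes(0, 0, 10, 10, score = 0.9),
                          boxes(0, 1, 10, 11, score = 0.8))
  cc3 <- match_detections(dup, gts[1, ], 0.5)
  expect_equal(c(cc3$tp, cc3$fp), c(1, 1))
})

test_that("the five indicators follow their formulas", {
  perfect <- compute_metrics(confusion_counts(1, 0, 1, 0))
  expect_true(all(perfect == 1))

  half <- compute_metrics(confusion_counts(25, 25, 25, 25))
  expect_true(all(half == 0.5))

  m <- compute_metrics(confusion_counts(9, 3, 7, 1))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$precision, 0.75)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$accuracy, 16 / 20)
  expect_equal(m$f1, 2 * 0.75 * 0.9 / 1.65)
  expect_gte(m$f1, min(m$precision, m$sensitivity))
  expect_lte(m$f1, max(m$precision, m$sensitivity))
})

test_that("undefined indicators are flagged, never reported as zero", {
  no_pos <- compute_metrics(confusion_counts(0, 0, 5, 0))
  expect_true(is.na(no_pos$precision))
  expect_true(is.na(no_pos$sensitivity))
  expect_equal(no_pos$specificity, 1)
  no_tn <- compute_metrics(confusion_counts(3, 1, NA, 2))
  expect_true(is.na(no_tn$accuracy))
  expect_true(is.na(no_tn$specificity))
  expect_false(is.na(no_tn$f1))
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "all-zero")
  expect_error(confusion_counts(-1, 0, 0, 0), ">= 0")
})

test_that("indicators match a per-sample counting oracle on random vectors", {
  withr::with_seed(41, {
    for (trial in 1:1000) {
      n <- sample(4:60, 1)
      truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
      pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
      tp <- sum(pred == 1 & truth == 1); fp <- sum(pred == 1 & truth == 0)
      tn <- sum(pred == 0 & truth == 0); fn <- sum(pred == 0 & truth == 1)
      if (tp + fp + tn + fn == 0) next
      m <- compute_metrics(confusion_counts(tp, fp, tn, fn))
      expect_equal(m$accuracy, mean(pred == truth))
      if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
      if (tp + fn > 0) expect_equal(m$sensitivity, mean(pred[truth == 1] == 1))
      if (fp + tn > 0) expect_equal(m$specificity, mean(pred[truth == 0] == 0))
    }
  })
})

test_that("the harmonic-mean helper agrees with the indicator path", {
  expect_equal(round(f1_from_pr(0.9421, 0.9540), 4), 0.9480)
  expect_equal(round(f1_from_pr(0.9463, 0.9582), 4), 0.9522)
  expect_equal(f1_from_pr(0.37, 0.37), 0.37)
  expect_error(f1_from_pr(0, 0), "> 0")
  withr::with_seed(13, {
    for (trial in 1:50) {
      tp <- sample(1:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
      m <- compute_metrics(confusion_counts(tp, fp, NA, fn))
      expect_equal(f1_from_pr(m$precision, m$sensitivity), m$f1)
    }
  })
})

test_that("fold assignment is balanced, exact and deterministic", {
  f <- kfold_split(10, 5, seed = 1)
  expect_equal(unname(table(f)), rep(2L, 5), ignore_attr = TRUE)
  expect_length(f, 10)
  g <- kfold_split(23, 5, seed = 7)
  expect_true(max(table(g)) - min(table(g)) <= 1)
  expect_setequal(unique(g), 1:5)
  expect_identical(kfold_split(23, 5, seed = 7), g)
  expect_false(identical(kfold_split(23, 5, seed = 8), g))
  expect_error(kfold_split(3, 5), "exceed")
})

test_that("fold summaries pool counts before recomputing indicators", {
  counts <- list(confusion_counts(8, 2, 5, 1), confusion_counts(4, 4, 9, 3))
  s <- summarize_folds(counts)
  expect_equal(nrow(s), 3)
  pooled <- s[s$fold == "pooled", ]
  expect_equal(pooled$precision, 12 / (12 + 6))
  expect_equal(pooled$sensitivity, 12 / (12 + 4))
})

test_that("printed benchmark rows satisfy the F1 identity except one known typo", {
  res <- check_f1_consistency()
  expect_equal(nrow(res), 40)
  failed <- res[!res$pass, ]
  # a single row (MobileNet + k-means, K = 5) is internally inconsistent as
  # printed; every other row reproduces its F1 cell to 4 decimals
  expect_equal(nrow(failed), 1)
  expect_equal(failed$table, 5L)
  expect_equal(failed$setting, "K=5")
  expect_gt(failed$abs_diff, 1e-4)

  # negative control: perturbing a consistent row must flip it to FAIL
  tweaked <- nodule_benchmark_tables()
  tweaked$precision[tweaked$table == 2 & tweaked$setting == "K=5"] <-
    tweaked$precision[tweaked$table == 2 & tweaked$setting == "K=5"] + 0.01
  res2 <- check_f1_consistency(tweaked)
  expect_false(res2$pass[res2$table == 2 & res2$setting == "K=5"])
})
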