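test_that("membership degrees follow the fuzzy update rule", {
  # equidistant from two centres
  u <- fcm_memberships(box_wh(5, 5), box_wh(c(4, 6), c(5, 5)), m = 2)
  expect_equal(as.vector(u), c(0.5, 0.5))
  # coincident with the first centre
  u2 <- fcm_memberships(box_wh(4, 5), box_wh(c(4, 6, 9), c(5, 5, 5)), m = 2)
  expect_equal(as.vector(u2), c(1, 0, 0))
  # distances (1, 2): memberships (0.8, 0.2)
  u3 <- fcm_memberships(box_wh(3, 4), box_wh(c(3, 3), c(5, 2)), m = 2)
  expect_equal(as.vector(u3), c(0.8, 0.2))
  expect_error(fcm_memberships(box_wh(1, 1), box_wh(2, 2), m = 1), "m must be")
})

test_that("membership rows are a unit partition on random instances", {
  withr::with_seed(21, {
    for (trial in 1:50) {
      n <- sample(2:40, 1); c <- sample(1:5, 1)
      pts <- box_wh(runif(n, 1, 50), runif(n, 1, 50))
      ctr <- box_wh(runif(c, 1, 50), runif(c, 1, 50))
      m <- runif(1, 1.1, 4)
      u <- fcm_memberships(pts, ctr, m)
      expect_true(all(u >= 0 & u <= 1))
      expect_true(all(abs(rowSums(u) - 1) < 1e-9))
    }
  })
})

test_that("fuzzy c-means recovers well-separated blob centres", {
  withr::with_seed(4, {
    blob1 <- box_wh(rnorm(40, 10, 0.5), rnorm(40, 12, 0.5))
    blob2 <- box_wh(rnorm(40, 40, 0.5), rnorm(40, 35, 0.5))
  })
  pts <- dplyr::bind_rows(blob1, blob2)
  fit <- fcm_fit(pts, c = 2, m = 2, seed = 1)
  ctr <- fit$anchors$shapes[order(fit$anchors$shapes$width), ]
  expect_lt(abs(ctr$width[1] - mean(blob1$width)), 1.5)
  expect_lt(abs(ctr$height[1] - mean(blob1$height)), 1.5)
  expect_lt(abs(ctr$width[2] - mean(blob2$width)), 1.5)
  expect_lt(abs(ctr$height[2] - mean(blob2$height)), 1.5)
  expect_true(fit$converged)
})

test_that("a single fuzzy cluster sits at the mean for any fuzzifier", {
  pts <- box_wh(c(2, 4, 9, 13), c(1, 7, 3, 5))
  for (m in c(1.3, 2, 3.5)) {
    fit <- fcm_fit(pts, c = 1, m = m, seed = 1)
    expect_equal(fit$anchors$shapes$width, mean(pts$width), tolerance = 1e-6)
    expect_equal(fit$anchors$shapes$height, mean(pts$height), tolerance = 1e-6)
  }
})

test_that("fuzzy fits are deterministic and validated", {
  pts <- box_wh(runif(30, 1, 20), runif(30, 1, 20))
  a <- fcm_fit(pts, c = 3, m = 2, seed = 7)
  b <- fcm_fit(pts, c = 3, m = 2, seed = 7)
  expect_identical(a$anchors$shapes, b$anchors$shapes)
  expect_identical(a$memberships, b$memberships)
  expect_error(fcm_fit(box_wh(1, 1), c = 2), "at least c")
})

test_that("the fuzzy objective never increases across iterations", {
  withr::with_seed(14, {
    for (trial in 1:5) {
      pts <- box_wh(runif(60, 1, 60), runif(60, 1, 60))
      fit <- fcm_fit(pts, c = sample(2:5, 1), m = 2, seed = trial)
      expect_true(all(diff(fit$objective) <= 1e-9))
    }
  })
})

test_that("the crisp limit of fuzzy assignments matches k-means on separated blobs", {
  withr::with_seed(8, {
    blob1 <- box_wh(rnorm(30, 8, 0.4), rnorm(30, 8, 0.4))
    blob2 <- box_wh(rnorm(30, 30, 0.4), rnorm(30, 28, 0.4))
  })
  pts <- dplyr::bind_rows(blob1, blob2)
  fz <- fcm_fit(pts, c = 2, m = 1.05, seed = 2)
  km <- kmeans_fit(pts, k = 2, seed = 2)
  fuzzy_assign <- apply(fz$memberships, 1, which.max)
  # compare as partitions (cluster ids may be permuted)
  expect_equal(length(unique(paste(fuzzy_assign, km$cluster))), 2)
})

test_that("fuzzy centres agree with an independent implementation", {
  withr::with_seed(31, {
    pts <- dplyr::bind_rows(
      box_wh(rnorm(50, 10, 1), rnorm(50, 12, 1)),
      box_wh(rnorm(50, 30, 1), rnorm(50, 26, 1)))
  })
  ours <- fcm_fit(pts, c = 2, m = 2, seed = 1)
  theirs <- withr::with_seed(31,
    e1071::cmeans(cbind(pts$width, pts$height), centers = 2, m = 2))
  ours_sorted <- as.matrix(ours$anchors$shapes[order(ours$anchors$shapes$width), ])
  theirs_sorted <- theirs$centers[order(theirs$centers[, 1]), ]
  expect_equal(unname(ours_sorted), unname(theirs_sorted), tolerance = 1e-2)
})

test_that("k-means attains the exhaustive-partition optimum on tiny instances", {
  withr::with_seed(17, {
    for (trial in 1:8) {
      n <- sample(4:8, 1); k <- sample(2:3, 1)
      pts <- box_wh(runif(n, 1, 30), runif(n, 1, 30))
      fit <- kmeans_fit(pts, k = k, seed = trial)
      opt <- brute_force_inertia(cbind(pts$width, pts$height), k)
      expect_equal(fit$inertia, opt, tolerance = 1e-8)
    }
  })
})

test_that("k-means degenerate cases behave", {
  pts <- box_wh(c(1, 5, 9), c(2, 6, 10))
  fit <- kmeans_fit(pts, k = 3, seed = 1)
  expect_equal(fit$inertia, 0)
  expect_setequal(fit$anchors$shapes$width, pts$width)

  same <- box_wh(rep(4, 6), rep(7, 6))
  fit2 <- kmeans_fit(same, k = 2, seed = 1)
  expect_true(all(fit2$anchors$shapes$width == 4))
  expect_true(all(fit2$anchors$shapes$height == 7))
  expect_error(kmeans_fit(box_wh(1, 1), k = 2), "at least k")
})

test_that("mean best IoU scores anchor coverage", {
  pop <- box_wh(c(4, 10, 30), c(4, 12, 28))
  expect_equal(mean_best_iou(pop, pop), 1.0)
  expect_equal(mean_best_iou(box_wh(2, 2), box_wh(2, 4)), 0.5)
  a1 <- box_wh(5, 5)
  a2 <- box_wh(c(5, 28), c(5, 30))
  expect_gte(mean_best_iou(pop, a2), mean_best_iou(pop, a1))
  expect_error(mean_best_iou(box_wh(), pop), "nonempty")
})

test_that("fuzzy clustering recovers both modes of a two-component population", {
  comp <- two_mode_components()
  b <- sample_nodule_boxes(500, comp, seed = 9)
  fit <- fcm_fit(b[, c("width", "height")], c = 2, m = 2, seed = 1)
  ctr <- fit$anchors$shapes[order(fit$anchors$shapes$width), ]
  truth_w <- exp(comp$mean_log_w + comp$log_sd^2 / 2)
  truth_h <- exp(comp$mean_log_h + comp$log_sd^2 / 2)
  expect_lt(abs(ctr$width[1] - truth_w[1]) / truth_w[1], 0.1)
  expect_lt(abs(ctr$height[1] - truth_h[1]) / truth_h[1], 0.1)
  expect_lt(abs(ctr$width[2] - truth_w[2]) / truth_w[2], 0.1)
  expect_lt(abs(ctr$height[2] - truth_h[2]) / truth_h[2], 0.1)
})

test_that("the IoU clustering distance is available", {
  u <- fcm_memberships(box_wh(4, 4), box_wh(c(4, 8), c(4, 8)), m = 2,
                       dist = "iou")
  expect_gt(u[1, 1], u[1, 2])
  fit <- fcm_fit(box_wh(runif(20, 2, 20), runif(20, 2, 20)), c = 2,
                 seed = 3, dist = "iou")
  expect_equal(nrow(fit$anchors$shapes), 2)
})
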