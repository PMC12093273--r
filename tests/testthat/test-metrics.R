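test_that("classification metrics follow the confusion-count formulas", {
  perfect <- classification_metrics(5, 5, 0, 0)
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1, specificity = 1))
  worst <- classification_metrics(0, 0, 5, 5)
  expect_equal(unlist(worst), c(accuracy = 0, sensitivity = 0, specificity = 0))
  mixed <- classification_metrics(3, 4, 2, 1)
  expect_equal(mixed$accuracy, 0.7)
  expect_equal(mixed$sensitivity, 0.75)
  expect_equal(mixed$specificity, 2 / 3)
  expect_error(classification_metrics(0, 5, 5, 0), "sensitivity")
  expect_error(classification_metrics(5, 0, 0, 5), "specificity")
  expect_error(classification_metrics(-1, 2, 2, 2), "non-negative")
})

test_that("AUC follows the rank formulation with tie handling", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc(c(1, 2, 3), c(1, 1, 1)), "both classes")
})

test_that("rank-based AUC equals the brute-force pairwise comparison", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), sample(c(1, 3), 1)) # coarse rounding forces ties
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc(scores, labels), mean(cmp))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(42)
  scores <- rnorm(30)
  labels <- sample(c(0, 1), 30, replace = TRUE)
  labels[1:2] <- c(0, 1)
  expect_equal(auc(exp(scores), labels), auc(scores, labels))
  expect_equal(auc(scores * 100 - 3, labels), auc(scores, labels))
})

test_that("dice follows set arithmetic with documented empty conventions", {
  a <- array(0L, c(4, 4, 4)); a[1:2, , ] <- 1L
  expect_equal(dice(a, a), 1)
  b <- array(0L, c(4, 4, 4)); b[3:4, , ] <- 1L
  expect_equal(dice(a, b), 0)
  st <- array(0L, c(4, 4, 4)); st[1:2, 1:2, 1:2] <- 1L      # |St| = 8
  sg <- array(0L, c(4, 4, 4)); sg[2:3, 1:2, 1:2] <- 1L      # |Sg| = 8, overlap 4
  expect_equal(dice(st, sg), 0.5)
  expect_equal(dice(st, sg), dice(sg, st))
  empty <- array(0L, c(4, 4, 4))
  expect_equal(dice(empty, empty), 1)
  expect_equal(dice(empty, a), 0)
  expect_error(dice(a, array(0L, c(4, 4, 5))), "shape")
})

test_that("dice agrees with direct set arithmetic on random masks", {
  set.seed(43)
  for (rep in 1:10) {
    a <- array(as.integer(runif(6^3) > 0.6), c(6, 6, 6))
    b <- array(as.integer(runif(6^3) > 0.6), c(6, 6, 6))
    oracle <- 2 * sum(a & b) / (sum(a) + sum(b))
    expect_equal(dice(a, b), oracle)
  }
})

test_that("average Euclidean distance is the mean over matched pairs", {
  pts <- tibble::tibble(x = c(1, 10), y = c(2, 2), z = c(3, 3))
  expect_equal(avg_euclidean_distance(pts, pts), 0)
  expect_equal(avg_euclidean_distance(c(0, 0, 0), c(3, 4, 0), diff = 10), 5)
  expect_error(avg_euclidean_distance(c(0, 0, 0), c(30, 40, 0), diff = 10),
               "no matched")
  expect_error(avg_euclidean_distance(pts, pts, diff = 0))
})

test_that("average distance equals the exhaustive-assignment oracle and respects diff", {
  for (seed in 21:30) {
    inst <- sparse_match_instance(seed)
    oracle <- brute_force_match(inst$gt, inst$pred, 10)
    if (oracle$n == 0) {
      expect_error(avg_euclidean_distance(inst$gt, inst$pred, 10))
    } else {
      got <- avg_euclidean_distance(inst$gt, inst$pred, 10)
      expect_equal(got, mean(oracle$pairs[, 3]))
      expect_lte(got, 10)
    }
  }
})

test_that("detection metrics support both denominator conventions", {
  all_perfect <- detection_metrics(10, 10, 10)
  expect_equal(unlist(all_perfect[1:3]), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(unlist(detection_metrics(10, 10, 10, "conventional")[1:3]),
               c(precision = 1, recall = 1, f1 = 1))

  ap <- detection_metrics(10, 8, 8)
  expect_equal(ap$precision, 0.8)
  expect_equal(ap$recall, 1)
  expect_equal(ap$f1, 2 * 0.8 / 1.8)
  conv <- detection_metrics(10, 8, 8, "conventional")
  expect_equal(conv$precision, 1)
  expect_equal(conv$recall, 0.8)
  # F1 is symmetric in the two rates, so identical across conventions
  set.seed(44)
  for (rep in 1:10) {
    n_gt <- sample(3:20, 1); n_det <- sample(3:20, 1)
    n_tp <- sample(0:min(n_gt, n_det), 1)
    if (n_tp == 0) next
    expect_equal(detection_metrics(n_gt, n_tp, n_det)$f1,
                 detection_metrics(n_gt, n_tp, n_det, "conventional")$f1)
  }
  expect_error(detection_metrics(5, 6, 5), "exceed")
  expect_error(detection_metrics(0, 0, 5))
})

test_that("rate metrics stay in [0, 1] and F1 sits between the rates", {
  set.seed(45)
  for (rep in 1:20) {
    n_gt <- sample(1:30, 1); n_det <- sample(1:30, 1)
    n_tp <- sample(0:min(n_gt, n_det), 1)
    m <- detection_metrics(n_gt, n_tp, n_det)
    expect_true(all(unlist(m[1:3]) >= 0 & unlist(m[1:3]) <= 1))
    if (m$precision > 0 && m$recall > 0) {
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    }
  }
})
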