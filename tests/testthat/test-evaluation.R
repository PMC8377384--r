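test_that("metrics match their closed forms on enumerated confusion tables", {
  # perfect classifier
  m <- binary_metrics(rep(c(1, 0), each = 10), rep(c(1, 0), each = 10))
  expect_equal(unlist(m[c("recall", "precision", "acc", "mcc")]),
               c(recall = 1, precision = 1, acc = 1, mcc = 1))

  # fully symmetric table: TP=TN=FP=FN=25 forces MCC to 0
  y <- rep(c(1, 1, 0, 0), each = 25)
  p <- rep(c(1, 0, 1, 0), each = 25)
  m <- binary_metrics(y, p)
  expect_equal(m$acc, 0.5)
  expect_equal(m$mcc, 0)

  # TP=40, FN=10, TN=35, FP=15 evaluated from the closed forms
  y <- c(rep(1, 50), rep(0, 50))
  p <- c(rep(1, 40), rep(0, 10), rep(1, 15), rep(0, 35))
  m <- binary_metrics(y, p)
  expect_equal(m$recall, 0.8)
  expect_equal(m$precision, 40 / 55)
  expect_equal(m$acc, 0.75)
  expect_equal(m$mcc, (40 * 35 - 15 * 10) / sqrt(55 * 45 * 50 * 50),
               tolerance = 1e-12)
  expect_false(m$degenerate)
})

test_that("zero-denominator metrics report 0 with a degeneracy flag", {
  m <- binary_metrics(c(0, 0, 0), c(0, 0, 0))
  expect_equal(m$recall, 0)
  expect_equal(m$precision, 0)
  expect_equal(m$acc, 1)
  expect_true(m$degenerate)
  expect_error(binary_metrics(c(1, 0), c(1)), "lengths differ")
})

test_that("curve areas hit their analytic endpoints", {
  y <- c(0, 0, 1, 1)
  cv <- curves_and_auc(y, c(0.1, 0.2, 0.8, 0.9))
  expect_equal(cv$auroc, 1)
  expect_equal(cv$auprc, 1)
  # one tie group: chance-level area
  cv <- curves_and_auc(y, rep(0.5, 4))
  expect_equal(cv$auroc, 0.5)
  expect_error(curves_and_auc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("the ROC area equals the normalized Mann-Whitney statistic", {
  set.seed(30)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    y <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
    expect_equal(curves_and_auc(y, s)$auroc, oracle_auroc(y, s),
                 tolerance = 1e-12)
  }
})

test_that("the ROC area is invariant under strictly monotone score transforms", {
  set.seed(31)
  y <- sample(c(0L, 1L), 50, replace = TRUE)
  s <- rnorm(50)
  a0 <- curves_and_auc(y, s)$auroc
  expect_equal(curves_and_auc(y, 10 * s - 3)$auroc, a0, tolerance = 1e-12)
  expect_equal(curves_and_auc(y, plogis(s))$auroc, a0, tolerance = 1e-12)
  expect_equal(curves_and_auc(y, exp(s))$auroc, a0, tolerance = 1e-12)
})

test_that("metric ranges hold across random confusion vectors", {
  set.seed(32)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    m <- binary_metrics(sample(c(0L, 1L), n, replace = TRUE),
                        sample(c(0L, 1L), n, replace = TRUE))
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    expect_true(m$acc >= 0 && m$acc <= 1)
    expect_equal(m$tp + m$tn + m$fp + m$fn, n)
  }
})

test_that("stratified folds partition pairs with balanced classes", {
  set.seed(33)
  y <- rep(c(0L, 1L), each = 50)
  fold <- ppiboost:::stratified_folds(y, k = 5, seed = 1)
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) == 20))
  expect_true(all(table(fold, y) == 10))
  expect_identical(fold, ppiboost:::stratified_folds(y, k = 5, seed = 1))
  expect_error(ppiboost:::stratified_folds(c(0L, 1L, 1L, 1L), k = 3), "minority")
})

test_that("cross-validation audits folds and is reproducible", {
  set.seed(34)
  n <- 100; d <- 30
  x <- matrix(rnorm(n * d), n, d)
  y <- as.integer(x[, 1] * 2 + rnorm(n, sd = 0.6) > 0)
  cv1 <- cross_validate(x, y, k = 5, M = 30, seed = 7)
  cv2 <- cross_validate(x, y, k = 5, M = 30, seed = 7)
  expect_identical(cv1$per_fold, cv2$per_fold)

  # every pair appears in exactly one test fold; sizes differ by <= 1
  expect_length(cv1$fold, n)
  expect_lte(diff(range(table(cv1$fold))), 1)

  # per-fold metrics aggregate into the summary
  expect_equal(nrow(cv1$per_fold), 5L)
  acc <- cv1$summary$mean[cv1$summary$metric == "acc"]
  expect_equal(acc, mean(cv1$per_fold$acc))
  expect_equal(glance(cv1)$mean_acc, acc)
  expect_equal(nrow(tidy(cv1)), 5L)

  # the selection support is refit per training fold (leakage sentinel):
  # fold-specific supports should not all be identical on noisy data
  expect_gt(length(unique(cv1$support_sizes)), 1L)
})

test_that("curve and report plots are well-formed ggplot objects", {
  set.seed(35)
  y <- sample(c(0L, 1L), 40, replace = TRUE)
  s <- runif(40)
  ev <- evaluate_predictions(y, s)
  expect_s3_class(autoplot(ev, "roc"), "ggplot")
  expect_s3_class(autoplot(ev$curves, "pr"), "ggplot")
  x <- matrix(rnorm(40 * 5), 40, 5)
  cv <- cross_validate(x, y, k = 2, M = 5, seed = 1)
  expect_s3_class(autoplot(cv, "roc"), "ggplot")
})
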