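test_that("confusion-matrix rates follow their defining identities", {
  cm <- confusion_matrix(tp = 272, fp = 13, tn = 340, fn = 23)
  r <- rates(cm)
  expect_equal(r$tpr, 272 / 295)
  expect_equal(r$fnr, 23 / 295)
  expect_equal(r$tpr, 0.92203, tolerance = 1e-5)
  expect_equal(r$fpr, 13 / 353)
  expect_equal(r$precision, 272 / 285)
  expect_identical(r$recall, r$tpr)
  perfect <- rates(confusion_matrix(10, 0, 10, 0))
  expect_equal(perfect$tpr, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$precision, 1)
  expect_true(is.nan(rates(confusion_matrix(0, 0, 5, 0))$tpr))
  expect_error(confusion_matrix(0, 0, 0, 0), "empty")
})

test_that("accuracy equals the brute-force agreement count", {
  expect_equal(accuracy(confusion_matrix(1, 0, 1, 0)), 1)
  set.seed(21)
  for (i in 1:5) {
    truth <- rbinom(60, 1, 0.5)
    pred <- rbinom(60, 1, 0.5)
    cm <- confusion_matrix(tp = sum(truth == 1 & pred == 1),
                           fp = sum(truth == 0 & pred == 1),
                           tn = sum(truth == 0 & pred == 0),
                           fn = sum(truth == 1 & pred == 0))
    expect_equal(accuracy(cm), mean(truth == pred))
  }
})

test_that("ROC AUC equals the Mann-Whitney pairwise probability", {
  # hand case: scores 1..6, labels 0,0,1,0,1,1
  sc <- 1:6; lb <- c(0, 0, 1, 0, 1, 1)
  roc <- roc_curve(sc, lb)
  expect_equal(roc$auc, mann_whitney_auc(sc, lb))
  # perfectly separated and fully tied cases
  expect_equal(roc_curve(c(1, 2, 3, 10, 11, 12),
                         c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_curve(rep(5, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)
  # random instances, with ties, against the exhaustive oracle
  set.seed(13)
  for (i in 1:30) {
    n <- sample(6:40, 1)
    sc <- sample(seq(0, 2, by = 0.1), n, replace = TRUE)
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    expect_equal(roc_curve(sc, lb)$auc, mann_whitney_auc(sc, lb))
  }
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC curve endpoints and monotone-transform invariance hold", {
  set.seed(17)
  sc <- rnorm(40); lb <- rbinom(40, 1, 0.5); lb[1:2] <- c(0, 1)
  roc <- roc_curve(sc, lb)
  last <- nrow(roc$points)
  expect_equal(roc$points$fpr[last], 1)
  expect_equal(roc$points$tpr[last], 1)
  expect_equal(roc_curve(exp(3 * sc), lb)$auc, roc$auc)
})

test_that("ROC/PR agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  sc <- round(rnorm(80), 1)
  lb <- rbinom(80, 1, 0.4); lb[1:2] <- c(0, 1)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(lb, sc,
                                                         direction = "<"))))
  expect_equal(roc_curve(sc, lb)$auc, ref, tolerance = 1e-12)
})

test_that("PR curve matches exhaustive precision/recall enumeration", {
  sc <- 1:6; lb <- c(0, 0, 1, 0, 1, 1)
  pr <- pr_curve(sc, lb)
  for (k in seq_len(nrow(pr$points))) {
    t <- pr$points$threshold[k]
    pred <- as.integer(sc >= t)
    expect_equal(pr$points$precision[k], sum(pred & lb) / sum(pred))
    expect_equal(pr$points$recall[k], sum(pred & lb) / sum(lb))
  }
  expect_equal(pr_curve(c(1, 2, 3, 10, 11, 12),
                        c(0, 0, 0, 1, 1, 1))$auc, 1)
  # all-positive labels: precision 1 at every threshold
  pr_all <- pr_curve(c(1, 2, 3), c(1, 1, 1))
  expect_true(all(pr_all$points$precision == 1))
})

test_that("optimal cutoffs maximize Youden's J and F1 with ties broken upward", {
  sc <- c(1.30, 1.42, 1.47, 1.55, 1.61, 1.68)
  lb <- c(0, 0, 1, 1, 1, 1)
  roc <- roc_curve(sc, lb)
  # exhaustive search over all candidate thresholds
  j <- vapply(sc, function(t) {
    mean(sc[lb == 1] >= t) - mean(sc[lb == 0] >= t)
  }, numeric(1))
  expect_equal(optimal_cutoff(roc), max(sc[j == max(j)]))
  pr <- pr_curve(sc, lb)
  f1 <- vapply(sc, function(t) {
    p <- sum(sc >= t & lb == 1) / sum(sc >= t)
    r <- sum(sc >= t & lb == 1) / sum(lb == 1)
    2 * p * r / (p + r)
  }, numeric(1))
  expect_equal(optimal_cutoff(pr), max(sc[f1 == max(f1)]))
  # degenerate one-threshold curve returns that threshold
  expect_equal(optimal_cutoff(roc_curve(rep(2, 4), c(0, 1, 0, 1))), 2)
})

test_that("group statistics reproduce the closed-form t interval", {
  g <- group_stats(c(1, 2, 3))
  expect_equal(g$group1$mean, 2)
  expect_equal(g$group1$ci, 2 + c(-1, 1) * 4.302653 * (1 / sqrt(3)),
               tolerance = 1e-6)
  two <- group_stats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(two$t_statistic, 0)
  expect_equal(two$p_value, 1)
  expect_false(two$significant)
  set.seed(23)
  shifted <- group_stats(rnorm(200), rnorm(200, mean = 1))
  expect_lt(shifted$p_value, 0.001)
  expect_true(shifted$significant)
  expect_error(group_stats(1), "n >= 2")
})

test_that("evaluate_scores summarizes a scored table coherently", {
  set.seed(29)
  df <- data.frame(fd = c(rnorm(30, 1.62, 0.03), rnorm(30, 1.40, 0.06)),
                   label = rep(c(1, 0), each = 30))
  ev <- evaluate_scores(df)
  expect_gt(ev$auc_roc, 0.9)
  expect_gt(ev$auc_pr, 0.9)
  expect_true(ev$cutoff_roc > 1.3 && ev$cutoff_roc < 1.7)
  expect_true(ev$group_stats$significant)
})
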