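# Confusion-matrix metrics, ROC/AUC, Hanley-McNeil standard errors, and the
# AUC power analysis.

test_that("confusion matrices count prediction/label pairs exactly", {
  all_right <- data.frame(label = rep(c("positive", "negative"), each = 10),
                          pred = rep(c("positive", "negative"), each = 10))
  cm <- confusion_from_predictions(all_right)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(10L, 0L, 10L, 0L))

  # flipping the labels swaps TP<->FN and TN<->FP
  flipped <- all_right
  flipped$label <- ifelse(flipped$label == "positive", "negative", "positive")
  cmf <- confusion_from_predictions(flipped)
  expect_equal(c(cmf$tp, cmf$fn, cmf$tn, cmf$fp), c(0L, 10L, 0L, 10L))

  # six hand rows with one FP and one FN, by enumeration
  hand <- data.frame(label = c("positive", "positive", "positive",
                               "negative", "negative", "negative"),
                     pred  = c("positive", "positive", "negative",
                               "negative", "negative", "positive"))
  cmh <- confusion_from_predictions(hand)
  expect_equal(c(cmh$tp, cmh$fn, cmh$tn, cmh$fp), c(2L, 1L, 2L, 1L))

  hand$label[2] <- NA
  expect_error(confusion_from_predictions(hand), "unlabeled")
})

test_that("metrics recompute the published table values from the confusion counts", {
  proposed <- metrics_from_cm(confusion_matrix(tp = 39, fn = 3, tn = 34, fp = 9))
  expect_equal(100 * proposed$accuracy, 85.88, tolerance = 0.005)
  expect_equal(100 * proposed$sensitivity, 92.86, tolerance = 0.005)
  expect_equal(100 * proposed$specificity, 79.07, tolerance = 0.005)
  expect_equal(proposed$f1, 0.8667, tolerance = 5e-5)

  baseline <- metrics_from_cm(confusion_matrix(tp = 36, fn = 6, tn = 28, fp = 15))
  expect_equal(100 * baseline$accuracy, 75.29, tolerance = 0.005)
  expect_equal(100 * baseline$sensitivity, 85.71, tolerance = 0.005)
  expect_equal(100 * baseline$specificity, 65.12, tolerance = 0.005)
  expect_equal(baseline$f1, 0.7742, tolerance = 5e-5)

  # degenerate denominators are undefined, never zero
  no_pos <- metrics_from_cm(confusion_matrix(tp = 0, fn = 0, tn = 5, fp = 2))
  expect_true(is.na(no_pos$sensitivity))
  expect_false(is.na(no_pos$specificity))
})

test_that("two computation paths agree: metrics from counts vs from predictions", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    tab <- data.frame(label = sample(c("positive", "negative"), n, replace = TRUE),
                      pred = sample(c("positive", "negative"), n, replace = TRUE))
    cm <- confusion_from_predictions(tab)
    m <- metrics_from_cm(cm)
    acc_direct <- mean(tab$label == tab$pred)
    expect_equal(m$accuracy, acc_direct, tolerance = 1e-12)
    if (!is.na(m$sensitivity))
      expect_equal(m$sensitivity,
                   mean(tab$pred[tab$label == "positive"] == "positive"),
                   tolerance = 1e-12)
  }
})

test_that("AUC is the Mann-Whitney statistic with half-credit ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       rep(c("negative", "positive"), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c("negative", "positive"), 3))$auc, 0.5)
  # positives {0.9, 0.4}, negatives {0.8, 0.1}: 3 of 4 pairs concordant
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.1),
                       c("positive", "positive", "negative", "negative"))$auc, 0.75)
  expect_error(roc_auc(c(1, 2), c("positive", "positive")), "both classes")
})

test_that("ROC endpoints, trapezoid agreement, monotone invariance, pROC cross-check", {
  set.seed(22)
  for (i in 1:15) {
    n <- sample(6:30, 1)
    scores <- round(runif(n), 2)                       # rounded so ties occur
    labels <- c("positive", "negative",
                sample(c("positive", "negative"), n - 2, replace = TRUE))
    ra <- roc_auc(scores, labels)
    expect_equal(ra$roc$fpr[1], 0); expect_equal(ra$roc$tpr[1], 0)
    expect_equal(ra$roc$fpr[nrow(ra$roc)], 1); expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
    expect_equal(ra$auc, trapezoid_auc(ra$roc), tolerance = 1e-10)
    # strictly monotone transforms leave the AUC unchanged
    expect_equal(roc_auc(exp(3 * scores) + 2, labels)$auc, ra$auc, tolerance = 1e-12)
    # independent implementation
    pr <- suppressMessages(pROC::roc(response = factor(labels, c("negative", "positive")),
                                     predictor = scores, quiet = TRUE,
                                     direction = "<"))
    expect_equal(ra$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  }
})

test_that("Hanley-McNeil standard error: closed form at 0.5 and the published band", {
  # at A = 0.5, Q1 = Q2 = 1/3 and SE^2 = (1/4 + (n-1)/12 + (n-1)/12) / n^2
  for (n in c(5, 20, 60)) {
    expect_equal(auc_standard_error(0.5, n, n),
                 sqrt((0.25 + (n - 1) / 12 + (n - 1) / 12) / n^2), tolerance = 1e-12)
  }
  se <- auc_standard_error(0.9468, 42, 43)
  expect_gte(se, 0.024); expect_lte(se, 0.028)
  expect_error(auc_standard_error(1.2, 42, 43), "auc")
  expect_error(auc_standard_error(0.9, 1, 43), "n_pos")
})

test_that("Hanley-McNeil SE tracks a stratified bootstrap of the empirical AUC", {
  set.seed(23)
  mu <- sqrt(2) * qnorm(0.9468)                        # binormal model at the printed AUC
  pos <- rnorm(42, mean = mu); neg <- rnorm(43)
  labels <- rep(c("positive", "negative"), c(42, 43))
  scores <- c(pos, neg)
  a_hat <- roc_auc(scores, labels)$auc
  boot <- replicate(2000, {
    roc_auc(c(sample(pos, replace = TRUE), sample(neg, replace = TRUE)), labels)$auc
  })
  expect_equal(auc_standard_error(a_hat, 42, 43), sd(boot), tolerance = 0.15)
})

test_that("AUC power analysis reproduces the null case and grows monotonically", {
  null_case <- auc_power(0.5 + 1e-12, 42, 43, alpha = 0.05)
  expect_equal(null_case$z, 0, tolerance = 1e-6)
  expect_equal(null_case$power, 0.05, tolerance = 1e-6)

  # power is monotone in the AUC and in the class sizes
  grid_auc <- vapply(c(0.6, 0.7, 0.8, 0.9), function(a)
    auc_power(a, 20, 20)$power, numeric(1))
  expect_true(all(diff(grid_auc) > 0))
  grid_n <- vapply(c(5, 10, 20, 40), function(n)
    auc_power(0.7, n, n)$power, numeric(1))
  expect_true(all(diff(grid_n) > 0))

  # two-sided power is below one-sided at the same level
  expect_lt(auc_power(0.7, 20, 20, two_sided = TRUE)$power,
            auc_power(0.7, 20, 20)$power)
})

test_that("improvement report gives the published percentage-point deltas", {
  base <- metrics_from_cm(confusion_matrix(tp = 36, fn = 6, tn = 28, fp = 15))
  prop <- metrics_from_cm(confusion_matrix(tp = 39, fn = 3, tn = 34, fp = 9))
  rep <- improvement_report(base, prop)
  expect_equal(rep$delta_display[rep$metric == "accuracy"], 10.59)
  expect_equal(rep$delta_display[rep$metric == "specificity"], 13.95)
  same <- improvement_report(prop, prop)
  expect_true(all(same$delta_pp == 0))
})
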