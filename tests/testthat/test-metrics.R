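test_that("confusion metrics match the printed formulas on worked examples", {
  perfect <- confusion_metrics(confusion_counts(50, 50, 0, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$auc_balanced, 1)

  # TP=45 FP=5 TN=40 FN=10, evaluated by hand from the formulas
  r <- confusion_metrics(confusion_counts(tp = 45, tn = 40, fp = 5,
                                          fn = 10))
  expect_equal(r$mcc, 1750 / sqrt(50 * 55 * 45 * 50), tolerance = 1e-12)
  expect_equal(r$f1, 2 * (45 / 55) * (45 / 50) / (45 / 55 + 45 / 50),
               tolerance = 1e-12)
  expect_equal(r$auc_balanced, (45 / 55 + 40 / 45) / 2,
               tolerance = 1e-12)
  expect_equal(round(r$mcc, 4), 0.7035)
  expect_equal(round(r$f1, 4), 0.8571)
  expect_equal(round(r$auc_balanced, 4), 0.8535)
})

test_that("undefined ratios are flagged NA, not coerced to zero", {
  r <- confusion_metrics(confusion_counts(tp = 0, tn = 10, fp = 0,
                                          fn = 10))
  expect_true(is.na(r$precision))
  expect_true("precision" %in% r$undefined)
  expect_false(is.na(r$accuracy))
  expect_error(confusion_counts(0, 0, 0, 0), "sum to zero")
})

test_that("every rate matches a brute-force recount on random instances", {
  set.seed(41)
  for (i in 1:60) {
    inst <- random_confusion_instance(sample(2:50, 1))
    pred <- inst$pred; lab <- inst$lab
    cm <- tabulate_confusion(pred, lab)
    r <- confusion_metrics(cm)
    expect_equal(r$accuracy, mean(pred == lab))
    if (!is.na(r$precision))
      expect_equal(r$precision, mean(lab[pred]))
    if (!is.na(r$recall))
      expect_equal(r$recall, mean(pred[lab]))
    if (!is.na(r$mcc)) {
      # MCC as the Pearson correlation of the two binary vectors
      expect_equal(r$mcc, suppressWarnings(cor(as.numeric(pred),
                                               as.numeric(lab))),
                   tolerance = 1e-12)
    }
  }
})

test_that("MCC flips sign under single-side class swap, is stable under double swap", {
  cm <- confusion_counts(tp = 30, tn = 20, fp = 10, fn = 5)
  swapped_both <- confusion_counts(tp = 20, tn = 30, fp = 5, fn = 10)
  swapped_pred <- confusion_counts(tp = 10, tn = 5, fp = 30, fn = 20)
  m <- confusion_metrics(cm)$mcc
  expect_equal(confusion_metrics(swapped_both)$mcc, m)
  expect_equal(confusion_metrics(swapped_pred)$mcc, -m)
})

test_that("roc_auc reproduces hand-enumerated and limiting cases", {
  # 4 scores {0.9+, 0.8-, 0.7+, 0.1-}: 3 of 4 pos-neg pairs won
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 3), c(1, 1, 0)), 1)
  set.seed(1)
  s <- runif(4000); l <- rbinom(4000, 1, 0.5)  # independent scores
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.03)
  expect_warning(expect_true(is.na(roc_auc(1:3, c(1, 1, 1)))),
                 "single-class")
})

test_that("roc_auc equals the exhaustive pair-counting oracle (n <= 50)", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    scores <- sample(round(runif(n), 2))  # rounded: force ties
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auc(scores, labels),
                 oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("average precision matches hand computation and baselines", {
  # {0.9+, 0.5-, 0.4+}: AP = 1/2 * (1 + 2/3)
  expect_equal(pr_curve(c(0.9, 0.5, 0.4), c(1, 0, 1))$aupr,
               0.5 * (1 + 2 / 3), tolerance = 1e-12)
  expect_equal(pr_curve(c(3, 2, 1), c(1, 1, 0))$aupr, 1)
  set.seed(2)
  n <- 5000; p <- 0.2
  l <- rbinom(n, 1, p)
  expect_lt(abs(pr_curve(runif(n), l)$aupr - p), 0.05)
  expect_warning(expect_true(is.na(pr_curve(1:3, c(0, 0, 0))$aupr)),
                 "no positive")
})

test_that("average precision equals the rank-walk oracle with ties", {
  set.seed(43)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    scores <- sample(round(runif(n), 1), n, replace = FALSE)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) next
    expect_equal(pr_curve(scores, labels)$aupr,
                 oracle_ap(scores, labels), tolerance = 1e-12)
  }
})

test_that("cross-entropy loss is the printed formula", {
  expect_lt(cross_entropy_loss(1.0, 0.0), 1e-5)
  expect_equal(cross_entropy_loss(0.5, 0.5), log(2), tolerance = 1e-9)
  # all-positive batch at probability p reduces to -log p
  expect_equal(cross_entropy_loss(rep(0.3, 7), numeric(0)), -log(0.3),
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(numeric(0), numeric(0)), "empty")
  # random instances vs direct formula evaluation
  set.seed(44)
  for (i in 1:20) {
    m <- sample(1:25, 1); n <- sample(1:25, 1)
    pp <- runif(m); np <- runif(n)
    direct <- -(sum(log(pp)) + sum(log(1 - np))) / (m + n)
    expect_equal(cross_entropy_loss(pp, np), direct,
                 tolerance = 1e-9)
  }
})

test_that("auc_balanced equals balanced accuracy of the thresholded scores", {
  set.seed(45)
  scores <- runif(200); labels <- rbinom(200, 1, 0.4)
  r <- evaluate_scores(scores, labels)
  pred <- scores > 0.5
  bal <- (mean(pred[labels == 1]) + mean(!pred[labels == 0])) / 2
  expect_equal(r$auc_balanced, bal)
  # ranking AUC and threshold AUC are distinct quantities
  expect_false(isTRUE(all.equal(r$auc_balanced, r$auc_roc)))
})

test_that("metric_table serializes one row per report", {
  r1 <- evaluate_scores(c(0.9, 0.2, 0.8, 0.1), c(1, 0, 1, 0))
  r2 <- confusion_metrics(confusion_counts(5, 5, 2, 1))
  tab <- metric_table(list(r1, r2),
                      info = data.frame(target = c("AChE", "BuChE")))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("target", "mcc", "aupr", "tp") %in% names(tab)))
  expect_true(is.na(tab$aupr[2]))
})
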