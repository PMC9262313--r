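test_that("AUC on elementary configurations", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(c(2, 3, 1, 2.5), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "echopvr_insufficient_data")
})

test_that("AUC equals brute-force pair concordance on random instances", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(1:10, n, replace = TRUE)  # heavy ties
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("curve is a valid ROC whose trapezoidal area equals the AUC", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    scores <- round(rnorm(n), 1)
    r <- roc_auc(scores, labels)
    cv <- r$curve
    expect_equal(cv[1, ], data.frame(fpr = 0, tpr = 0), ignore_attr = TRUE)
    expect_equal(unlist(cv[nrow(cv), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
    trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:15) {
    n <- sample(10:60, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    scores <- rnorm(n, mean = labels)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("Youden cutoff maximizes J with ties broken toward sensitivity", {
  y1 <- youden_cutoff(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(y1$cutoff, 3)
  expect_equal(y1$sensitivity, 1)
  expect_equal(y1$specificity, 1)

  y2 <- youden_cutoff(c(2, 3, 1, 2.5), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(y2$cutoff, 2)  # J ties at 2 and 3; lower cutoff wins
  expect_equal(y2$j, 0.5)
  expect_equal(y2$sensitivity, 1)

  y3 <- youden_cutoff(rep(2, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(y3$j, 0)

  # exhaustive-search oracle on random instances
  set.seed(53)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(1:8, n, replace = TRUE)
    got <- youden_cutoff(scores, labels)
    js <- vapply(sort(unique(scores)), function(t) {
      mean(scores[labels] >= t) + mean(scores[!labels] < t) - 1
    }, numeric(1))
    expect_equal(got$j, max(js), tolerance = 1e-12)
  }
})

test_that("AUC and Youden J are invariant under increasing transforms", {
  set.seed(61)
  labels <- runif(40) < 0.4
  labels[1:2] <- c(TRUE, FALSE)
  scores <- rnorm(40, mean = labels)
  for (f in list(function(x) 3 * x + 2, exp, function(x) x^3)) {
    expect_equal(roc_auc(f(scores), labels)$auc, roc_auc(scores, labels)$auc,
                 tolerance = 1e-12)
    expect_equal(youden_cutoff(f(scores), labels)$j,
                 youden_cutoff(scores, labels)$j, tolerance = 1e-12)
  }
})

test_that("roc_analysis bundles AUC, CI and operating point", {
  set.seed(71)
  labels <- rep(c(TRUE, FALSE), each = 30)
  scores <- rnorm(60, mean = labels)
  r <- roc_analysis(scores, labels)
  expect_true(r$auc_ci_low <= r$auc && r$auc <= r$auc_ci_high)
  expect_equal(r$auc, roc_auc(scores, labels)$auc)
  expect_equal(r$cutoff, youden_cutoff(scores, labels)$cutoff)
  expect_equal(r$n, 60)
})
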