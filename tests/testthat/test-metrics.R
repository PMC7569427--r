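test_that("confusion counts match direct enumeration", {
  truth <- matrix(c(1, 1, 0, 0), 1)
  probs <- matrix(c(0.9, 0.4, 0.6, 0.1), 1)
  cc <- confusion_counts(probs, truth, 0.5)
  expect_equal(cc$TP, 1L); expect_equal(cc$FN, 1L)
  expect_equal(cc$FP, 1L); expect_equal(cc$TN, 1L)
  # perfect and inverted predictions
  p2 <- matrix(c(0.9, 0.8, 0.1, 0.2), 1)
  cc2 <- confusion_counts(p2, truth)
  expect_equal(cc2$FP + cc2$FN, 0L)
  cc3 <- confusion_counts(1 - p2, truth, 0.4)
  expect_equal(cc3$TP + cc3$TN, 0L)
  expect_error(confusion_counts(matrix(0.5, 2, 2), truth), "shapes")
})

test_that("summary ratios follow their definitions, flagging 0/0", {
  mk <- function(TP, TN, FP, FN)
    structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
              class = "confusion_counts")
  r <- summarize_metrics(mk(50, 50, 0, 0))
  expect_equal(r$acc, 1); expect_equal(r$f1, 1)
  r2 <- summarize_metrics(mk(50, 0, 0, 50))
  expect_equal(r2$sens, 0.5)
  expect_true("spec" %in% r2$undefined)
  r3 <- summarize_metrics(mk(1, 1, 1, 1))
  expect_equal(unlist(r3[c("acc", "sens", "spec", "prec", "f1")]),
               c(acc = 0.5, sens = 0.5, spec = 0.5, prec = 0.5, f1 = 0.5))
  expect_error(summarize_metrics(mk(0, 0, 0, 0)), "no evaluated")
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(1)
  for (i in 1:20) {
    n <- 200
    probs <- matrix(runif(n), 10)
    truth <- matrix(rbinom(n, 1, 0.3), 10)
    r <- summarize_metrics(confusion_counts(probs, truth))
    prev <- mean(truth)
    expect_equal(r$acc, prev * r$sens + (1 - prev) * r$spec, tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals the all-pairs rank estimate, ties included", {
  ra <- roc_auc(matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)),
                matrix(c(0, 0, 1, 0, 1, 1)))
  expect_equal(ra$auc, 8 / 9, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:300) {
    n <- sample(4:50, 1)
    # discrete probabilities force ties
    p <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(roc_auc(p, y)$auc, rank_auc(p, y), tolerance = 1e-9)
  }
})

test_that("AUC extremes and degenerate inputs behave as specified", {
  y <- matrix(c(1, 1, 0, 0), 1)
  expect_equal(roc_auc(y, y)$auc, 1)
  expect_equal(roc_auc(matrix(0.5, 1, 4), y)$auc, 0.5)
  expect_error(roc_auc(matrix(0.5, 1, 4), matrix(1, 1, 4)), "negative")
  expect_error(roc_auc(matrix(0.5, 1, 4), matrix(0, 1, 4)), "positive")
})

test_that("AUC is invariant to strictly monotone transforms of the scores", {
  set.seed(3)
  p <- runif(80); y <- rbinom(80, 1, 0.4)
  base <- roc_auc(p, y)$auc
  expect_equal(roc_auc(plogis(5 * p - 2), y)$auc, base, tolerance = 1e-12)
  expect_equal(roc_auc(p^3, y)$auc, base, tolerance = 1e-12)
})

test_that("our AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  for (i in 1:5) {
    p <- runif(60); y <- rbinom(60, 1, 0.5)
    if (sum(y) %in% c(0, 60)) next
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(y, p, levels = c(0, 1), direction = "<",
                          quiet = TRUE))))
    expect_equal(roc_auc(p, y)$auc, ref, tolerance = 1e-9)
  }
})

test_that("fov masks restrict the evaluated pixels", {
  probs <- matrix(runif(100), 10)
  truth <- matrix(rbinom(100, 1, 0.5), 10)
  fov <- matrix(0L, 10, 10); fov[1:5, ] <- 1L
  cc <- confusion_counts(probs, truth, fov = fov)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 50L)
  full <- evaluate_map(probs, truth)
  expect_false(full$fov_restricted)
  sub <- evaluate_map(probs, truth, fov = fov)
  expect_true(sub$fov_restricted)
})
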