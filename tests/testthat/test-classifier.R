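twoClusters <- function(n = 10, gap = 5, sd = 0.1, seed = 1, p = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p, gap, sd), n, p),
             matrix(rnorm(n * p, -gap, sd), n, p))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c(1, -1), each = n))
}

test_that("z-score scaling uses train-only statistics with the population SD", {
  sc <- scaleFeatures(matrix(c(1, 2, 3), 3, 1), mode = "zscore")
  expect_equal(sc$train[, 1], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # test statistics come from the training set
  sc2 <- scaleFeatures(matrix(c(1, 2, 3), 3, 1), matrix(5, 1, 1), "zscore")
  expect_equal(sc2$test[1, 1], (5 - 2) / sqrt(2 / 3), tolerance = 1e-12)
  # minmax may leave the unit interval on unseen test values
  sc3 <- scaleFeatures(matrix(c(0, 1), 2, 1), matrix(2, 1, 1), "minmax")
  expect_equal(sc3$test[1, 1], 2)
  # identity mode and the zero-variance guard
  sc4 <- scaleFeatures(matrix(1:4, 2, 2), mode = "none")
  expect_equal(sc4$train, matrix(1:4, 2, 2))
  expect_warning(sc5 <- scaleFeatures(matrix(c(1, 1), 2, 1), mode = "zscore"),
                 "zero-variance")
  expect_equal(sc5$train[, 1], c(0, 0))
})

test_that("well-separated clusters and XOR are fit exactly by the RBF-SVM", {
  d <- twoClusters()
  m <- trainSVMRBF(d$x, d$y, cost = 1, gamma = 1, scaleMode = "none")
  pr <- predict(m, d$x)
  expect_equal(pr$label, d$y)
  xor <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  yx <- c(1, -1, -1, 1)
  mx <- trainSVMRBF(xor, yx, cost = 1e3, gamma = 1, scaleMode = "none")
  expect_equal(predict(mx, xor)$label, yx)
})

test_that("the decision function matches an independent SVM solver", {
  skip_if_not_installed("kernlab")
  d <- twoClusters(gap = 1.2, sd = 0.8, seed = 7)
  m <- trainSVMRBF(d$x, d$y, cost = 2, gamma = 0.5, scaleMode = "none")
  dv <- predict(m, d$x)$decision
  k <- kernlab::ksvm(d$x, factor(d$y, levels = c(1, -1)), type = "C-svc",
                     kernel = "rbfdot", kpar = list(sigma = 0.5),
                     C = 2, scaled = FALSE)
  kd <- kernlab::predict(k, d$x, type = "decision")[, 1]
  if (cor(dv, kd) < 0) kd <- -kd   # solvers may orient classes oppositely
  expect_lt(max(abs(dv - kd)), 1e-3)
  expect_equal(sign(dv), sign(kd))
})

test_that("duplicating every training point leaves the decision function unchanged", {
  d <- twoClusters(gap = 1.5, sd = 0.7, seed = 3)
  m1 <- trainSVMRBF(d$x, d$y, cost = 1, gamma = 0.5, scaleMode = "none")
  m2 <- trainSVMRBF(rbind(d$x, d$x), c(d$y, d$y), cost = 0.5, gamma = 0.5,
                    scaleMode = "none")
  # halving C while doubling the data keeps the same dual optimum,
  # up to the solver's working tolerance
  d1 <- predict(m1, d$x)$decision; d2 <- predict(m2, d$x)$decision
  expect_lt(max(abs(d1 - d2)), 5e-3)
  expect_equal(sign(d1), sign(d2))
})

test_that("prediction validates dimensions and resolves ties toward responder", {
  d <- twoClusters()
  m <- trainSVMRBF(d$x, d$y)
  expect_error(predict(m, matrix(0, 1, 3)), "dimension mismatch")
  # symmetric 2-point problem: mirrored test point flips the label
  x2 <- matrix(c(1, -1), 2, 1)
  m2 <- trainSVMRBF(x2, c(1, -1), cost = 10, gamma = 1, scaleMode = "none")
  expect_equal(predict(m2, matrix(c(2, -2), 2, 1))$label, c(1, -1))
  expect_equal(predict(m2, matrix(0, 1, 1))$label, 1L)  # dv 0 -> +1
})

test_that("single-class training input is an error", {
  expect_error(trainSVMRBF(matrix(rnorm(10), 5, 2), rep(1, 5)),
               "single class")
})

test_that("confusion metrics match the defining formulas", {
  m <- classifierMetrics(c(TP = 3, FN = 1, TN = 4, FP = 0))
  expect_equal(unname(m), c(0.75, 1, 7 / 8))
  # all-positive, all-correct: accuracy 1, specificity undefined
  expect_warning(m2 <- classifierMetrics(c(TP = 5, TN = 0, FP = 0, FN = 0)),
                 "specificity undefined")
  expect_equal(m2[["accuracy"]], 1)
  expect_true(is.nan(m2[["specificity"]]))
  expect_error(classifierMetrics(c(TP = -1, TN = 1, FP = 1, FN = 1)),
               "negative")
  # swapping class labels swaps sensitivity and specificity
  cc <- c(TP = 3, TN = 6, FP = 2, FN = 1)
  sw <- c(TP = 6, TN = 3, FP = 1, FN = 2)
  expect_equal(classifierMetrics(cc)[["sensitivity"]],
               classifierMetrics(sw)[["specificity"]])
})

test_that("confusionCounts treats responder as the positive class", {
  cc <- confusionCounts(c(1, 1, -1, -1), c(1, -1, 1, -1))
  expect_equal(cc, c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  cc2 <- confusionCounts(c("responder", "non_responder"),
                         c("responder", "responder"))
  expect_equal(unname(cc2), c(1L, 0L, 0L, 1L))
})

test_that("AUC is the tie-corrected Mann-Whitney probability", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))$auc, 1)
  expect_equal(rocAUC(c(0.9, 0.4, 0.8, 0.1), c(1, 1, -1, -1))$auc, 0.75)
  set.seed(10)
  for (i in 1:20) {
    y <- c(rep(1, 6), rep(-1, 7))
    s <- sample(seq(0, 1, 0.1), 13, replace = TRUE)  # forces ties
    expect_lt(abs(rocAUC(s, y)$auc - bruteAUC(s, y)), 1e-12)
  }
  expect_error(rocAUC(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC points step from (0,0) to (1,1) and trace the thresholds", {
  r <- rocAUC(c(0.9, 0.4, 0.8, 0.1), c(1, 1, -1, -1))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
})

test_that("cross-validation is stratified, deterministic, perfect when separable", {
  d <- twoClusters(n = 6, gap = 4, sd = 0.3, seed = 5)
  cv <- kfoldCV(d$x, d$y, k = 5, repeats = 5, seed = 11)
  expect_equal(cvSummary(cv)[["mean_accuracy"]], 1)
  expect_equal(cvSummary(cv)[["mean_auc"]], 1)
  expect_equal(cvRepeats(cv)$accuracy, rep(1, 5))
  cv2 <- kfoldCV(d$x, d$y, k = 5, repeats = 5, seed = 11)
  expect_identical(cv2@assignments, cv@assignments)
  expect_identical(cvSummary(cv2), cvSummary(cv))
  cv3 <- kfoldCV(d$x, d$y, k = 5, repeats = 5, seed = 12)
  expect_false(identical(cv3@assignments, cv@assignments))
  # every training set saw both classes
  for (r in seq_len(5)) for (f in seq_len(5))
    expect_length(unique(d$y[cv@assignments[, r] != f]), 2L)
})

test_that("metrics recomputed from stored confusion counts reproduce the report", {
  d <- twoClusters(n = 6, gap = 1, sd = 1.2, seed = 9)
  cv <- kfoldCV(d$x, d$y, k = 3, repeats = 2, seed = 4)
  reps <- cvRepeats(cv)
  for (i in seq_len(nrow(reps))) {
    m <- classifierMetrics(c(TP = reps$TP[i], TN = reps$TN[i],
                             FP = reps$FP[i], FN = reps$FN[i]))
    expect_equal(reps$accuracy[i], m[["accuracy"]])
    expect_equal(reps$sensitivity[i], m[["sensitivity"]])
    expect_equal(reps$specificity[i], m[["specificity"]])
  }
})

test_that("DeLong comparison: identity gives p = 1, arguments commute, power shows", {
  set.seed(21)
  y <- rep(c(1, -1), each = 30)
  a <- rnorm(60) + 1.2 * (y == 1)
  b <- rnorm(60) + 0.3 * (y == 1)
  same <- compareAUC(a, a, y)
  expect_equal(same$p_value, 1)
  ab <- compareAUC(a, b, y); ba <- compareAUC(b, a, y)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  # a clear AUC gap is detected in most replicates
  set.seed(22)
  rej <- 0L
  for (i in 1:40) {
    y2 <- rep(c(1, -1), each = 50)
    s1 <- rnorm(100) + 2.3 * (y2 == 1)   # AUC ~ 0.95
    s2 <- rnorm(100) + 0.74 * (y2 == 1)  # AUC ~ 0.70
    p <- suppressWarnings(compareAUC(s1, s2, y2)$p_value)
    rej <- rej + (!is.na(p) && p < 0.05)
  }
  expect_gt(rej / 40, 0.8)
})

test_that("degenerate DeLong variance (twin perfect curves) is flagged, never silent", {
  y <- rep(c(1, -1), each = 4)
  a <- c(4, 3.8, 3.6, 3.4, 1, 0.8, 0.6, 0.4)  # AUC 1
  b <- c(9, 8, 7, 6, 2, 1.5, 1.2, 1)          # AUC 1
  expect_warning(res <- compareAUC(a, b, y), "misleading|not computable")
  expect_true(is.na(res$p_value) || res$p_value == 1)
  expect_equal(res$aucA, 1)
})

test_that("univariate markers are oriented so AUC is at least one half", {
  y <- rep(c(1, -1), each = 5)
  v <- c(1:5, 6:10)   # responders score LOWER
  u <- univariateROC(v, y)
  expect_equal(u$orientation, -1)
  expect_gte(u$auc, 0.5)
})

test_that("comparative-CT fold changes follow the base-2 law", {
  expect_equal(ddctFoldChange(20, 18, 22, 18), 4)
  expect_equal(ddctFoldChange(25, 20, 30, 25), 1)
  f1 <- ddctFoldChange(20, 18, 22, 18)
  f2 <- ddctFoldChange(21, 18, 22, 18)
  expect_equal(f2, f1 / 2)
  expect_error(ddctFoldChange(-1, 18, 22, 18), "positive")
})
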