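test_that("RVM prior parameters are recovered from model-simulated variances", {
  a0 <- 2; b0 <- 1; d <- 10
  set.seed(42)
  s2 <- rf(5000, df1 = d, df2 = 2 * a0) / (a0 * b0)
  prior <- fitRVMPrior(s2, df = d)
  expect_lt(abs(prior@a - a0) / a0, 0.15)
  expect_lt(abs(prior@b - b0) / b0, 0.15)
  # invariant to feature order
  prior2 <- fitRVMPrior(rev(s2), df = d)
  expect_equal(prior2@a, prior@a)
  expect_equal(prior2@b, prior@b)
})

test_that("degenerate variance inputs are fit errors", {
  expect_error(fitRVMPrior(rep(0, 100), df = 10), "zero")
  expect_error(fitRVMPrior(rep(1, 100), df = 10), "constant|degenerate")
  expect_error(fitRVMPrior(rexp(10), df = 10), ">= 20")
})

test_that("moderated t reduces to the pooled two-sample t as the prior flattens", {
  set.seed(1)
  v <- matrix(rnorm(30 * 12, 8, 1), 30, 12,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("S%02d", 1:12)))
  x <- exprFixture(v, "mRNA", rep(c("responder", "non_responder"), each = 6))
  res <- rvmTTest(x, flatPrior(df = 10))
  for (i in c(1, 13, 30)) {
    tt <- t.test(v[i, 1:6], v[i, 7:12], var.equal = TRUE)
    expect_lt(abs(res$t_stat[i] - unname(tt$statistic)), 1e-9)
    expect_lt(abs(res$p_value[i] - tt$p.value), 1e-9)
  }
})

test_that("identical group means give t = 0 and p = 1", {
  v <- cbind(matrix(rnorm(20 * 3), 20, 3), matrix(0, 20, 3))
  v[, 4:6] <- v[, 1:3]
  colnames(v) <- sprintf("S%d", 1:6); rownames(v) <- sprintf("f%d", 1:20)
  x <- exprFixture(v, "mRNA", rep(c("responder", "non_responder"), each = 3))
  res <- rvmTTest(x, new("RVMPrior", a = 2, b = 1, logLik = 0,
                         nFeatures = 20L, df = 4))
  expect_true(all(res$t_stat == 0))
  expect_true(all(res$p_value == 1))
})

test_that("swapping group labels flips t and preserves p", {
  set.seed(2)
  sim <- generateCohort(syntheticSpec(seed = 2))
  prior <- fitRVMPrior(pooledVariances(sim$mirna), df = 10)
  res1 <- rvmTTest(sim$mirna, prior)
  ann2 <- sim$annotation
  ann2$group <- ifelse(ann2$group == "responder", "non_responder",
                       "responder")
  res2 <- rvmTTest(sim$mirna, prior, annotation = ann2)
  expect_equal(res2$t_stat, -res1$t_stat, tolerance = 1e-12)
  expect_equal(res2$p_value, res1$p_value, tolerance = 1e-12)
})

test_that("type-I error of the moderated test is calibrated on null data", {
  sim <- generateCohort(syntheticSpec(delta = 0, nMirnas = 2000, seed = 31))
  prior <- fitRVMPrior(pooledVariances(sim$mirna), df = 10)
  res <- rvmTTest(sim$mirna, prior)
  rate <- mean(res$p_value < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("variance moderation beats the ordinary t-test for power at small n", {
  set.seed(77)
  hitsRVM <- hitsT <- 0L
  for (rep in seq_len(200)) {
    n <- 8; planted <- 1:5
    sd <- 1 / sqrt(rgamma(40, 4, rate = 4 * 0.3^2))
    v <- matrix(rnorm(40 * n, 0, rep(sd, n)), 40, n)
    v[planted, 1:4] <- v[planted, 1:4] + 1.5
    dimnames(v) <- list(sprintf("f%d", 1:40), sprintf("S%d", 1:n))
    x <- exprFixture(v, "mRNA", rep(c("responder", "non_responder"),
                                    each = 4))
    prior <- fitRVMPrior(pooledVariances(x), df = n - 2)
    res <- rvmTTest(x, prior)
    hitsRVM <- hitsRVM + sum(res$p_value[planted] < 0.05)
    pT <- apply(v[planted, , drop = FALSE], 1L, function(r)
      t.test(r[1:4], r[5:8], var.equal = TRUE)$p.value)
    hitsT <- hitsT + sum(pT < 0.05)
  }
  expect_gte(hitsRVM, hitsT)
})

test_that("BH step-up matches hand computations and validates input", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(c(0.001, 0.5)), c(0.002, 0.5))
  expect_equal(bhFDR(0.2), 0.2)
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the DE screen applies strict thresholds and partitions by sign", {
  res <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    log2fc = c(0.6, -0.8, 0.5, 2.0),
    t_stat = c(3, -4, 2.5, 1),
    p_value = c(0.01, 0.001, 0.01, 0.2),
    fdr_q = c(0.02, 0.004, 0.02, 0.3))
  scr <- screenDE(res, log2fcMin = 0.5, pMax = 0.05)
  expect_identical(scr$up$feature_id, "a")     # d fails p, c is boundary
  expect_identical(scr$down$feature_id, "b")
  expect_false(scr$results$significant[scr$results$feature_id == "c"])
  all_sig <- rbind(scr$up, scr$down)
  expect_true(all(abs(all_sig$log2fc) > 0.5 & all_sig$p_value < 0.05))
  # ordering: descending |t|
  scr2 <- screenDE(res, log2fcMin = 0.4, pMax = 0.05)
  expect_identical(scr2$up$feature_id, c("a", "c"))
  expect_error(screenDE(res, log2fcMin = 0), "> 0")
})

test_that("optional q-value gate tightens the screen", {
  res <- data.frame(feature_id = c("a", "b"), log2fc = c(1, 1),
                    t_stat = c(5, 4), p_value = c(0.01, 0.04),
                    fdr_q = c(0.02, 0.08))
  scr <- screenDE(res, fdrMode = "gate", fdrMax = 0.05)
  expect_identical(scr$up$feature_id, "a")
})

test_that("hierarchical clustering merges closest pairs at the merge distance", {
  v <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("p0", "p1", "p10"), "S1"))
  h <- hierarchicalCluster(v, distance = "euclidean", linkage = "single")
  expect_equal(h$height, c(1, 9))
  expect_identical(sort(h$labels[-h$merge[1, ]]), c("p0", "p1"))
})

test_that("duplicate rows merge at height zero and heights are monotone", {
  set.seed(3)
  v <- matrix(rnorm(5 * 6), 5, 6,
              dimnames = list(sprintf("f%d", 1:5), sprintf("S%d", 1:6)))
  v[2, ] <- v[1, ]
  h <- hierarchicalCluster(v, "euclidean", "average")
  expect_equal(h$height[1], 0)
  expect_equal(length(h$height), nrow(v) - 1L)
  expect_true(all(diff(h$height) >= -1e-12))
})

test_that("correlation distance rejects constant features; Newick export parses", {
  v <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "b", "c"),
                                               sprintf("S%d", 1:4)))
  v["b", ] <- 5
  expect_error(hierarchicalCluster(v, "one_minus_pearson"), "constant")
  v["b", ] <- rnorm(4)
  h <- hierarchicalCluster(v, "one_minus_pearson", "complete")
  txt <- dendrogramNewick(h)
  tree <- ape::read.tree(text = txt)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})
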