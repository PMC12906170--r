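test_that("median-of-ratios size factors match analytic and oracle values", {
  m <- matrix(c(5, 10, 20, 5, 10, 20), ncol = 2,
              dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  expect_equal(unname(estimateSizeFactors(m)), c(1, 1))

  m2 <- cbind(s1 = c(4, 9, 25), s2 = 2 * c(4, 9, 25))
  expect_equal(unname(estimateSizeFactors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  set.seed(3)
  m3 <- matrix(rpois(600, 40) + 1L, nrow = 100, ncol = 6)
  expect_equal(unname(estimateSizeFactors(m3)), oracle_size_factors(m3),
               tolerance = 1e-12)

  # invariance to feature order; scaling one column scales its factor
  perm <- sample(nrow(m3))
  expect_equal(estimateSizeFactors(m3[perm, ]), estimateSizeFactors(m3))
  # scaling one library by c scales its factor relative to the others by c
  # (factors are defined up to the geometric-mean constraint)
  m4 <- m3
  m4[, 2] <- m4[, 2] * 3L
  sf3 <- unname(estimateSizeFactors(m3))
  sf4 <- unname(estimateSizeFactors(m4))
  expect_equal(sf4[2] / sf4[1], 3 * sf3[2] / sf3[1], tolerance = 1e-12)

  expect_error(estimateSizeFactors(matrix(c(0, 1, 1, 0), 2)), "cannot normalize")
})

test_that("moments dispersion reproduces hand arithmetic and floors at zero variance", {
  m <- matrix(rep(c(7, 7, 7), each = 2), nrow = 2)
  groups <- rep("a", 3)
  a <- estimateDispersions(m, rep(1, 3), groups)
  expect_equal(unname(a), rep(1e-8, 2))

  # one group (5,10,15): mu = 10, v = 25 -> alpha = 0.15
  m2 <- matrix(c(5, 10, 15), nrow = 1)
  expect_equal(unname(estimateDispersions(m2, rep(1, 3), rep("a", 3))), 0.15)

  # Poisson data at high mean: estimated dispersion near zero
  set.seed(5)
  m3 <- matrix(rpois(5000 * 6, 60), ncol = 6)
  a3 <- estimateDispersions(m3, rep(1, 6), rep(c("a", "b"), each = 3))
  expect_lte(median(a3), 0.02)
})

test_that("the Wald test reproduces closed-form arithmetic and symmetry", {
  m <- rbind(f1 = c(10, 10, 10, 40, 40, 40),
             f2 = c(20, 20, 20, 20, 20, 20))
  groups <- rep(c("A", "B"), each = 3)
  tab <- nbWaldTest(m, rep(1, 6), c(0, 0), groups, c("A", "B"))
  expect_equal(tab["f1", "log2FoldChange"], 2)
  expect_equal(tab["f1", "lfcSE"] * log(2), sqrt(1 / 30 + 1 / 120),
               tolerance = 1e-12)
  expect_equal(tab["f1", "stat"], log(4) / sqrt(1 / 30 + 1 / 120),
               tolerance = 1e-12)
  # equal counts: no change, p = 1
  expect_equal(tab["f2", "log2FoldChange"], 0)
  expect_equal(tab["f2", "pvalue"], 1)

  # swapping the contrast negates the fold change and preserves p
  rev <- nbWaldTest(m, rep(1, 6), c(0, 0), groups, c("B", "A"))
  expect_equal(rev$log2FoldChange, -tab$log2FoldChange)
  expect_equal(rev$pvalue, tab$pvalue)

  expect_error(nbWaldTest(m[, 1:4], rep(1, 4), c(0, 0),
                          c("A", "A", "A", "B"), c("A", "B")),
               ">= 2 samples")
})

test_that("null negative-binomial simulation is calibrated near nominal level", {
  set.seed(101)
  n <- 8000
  m <- matrix(rnbinom(n * 12, mu = 50, size = 1 / 0.05), ncol = 12)
  rownames(m) <- paste0("f", seq_len(n))
  groups <- rep(c("A", "B"), each = 6)
  tab <- nbDifferential(m, groups, c("A", "B"))
  rate <- mean(tab$pvalue < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(9)
  for (i in 1:3) {
    p <- runif(50)^2
    expect_equal(bhAdjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("threshold calling uses strict inequalities and matches a direct filter", {
  tab <- data.frame(log2FoldChange = c(1.2, 1.0, -1.4, 0.5),
                    pvalue = c(0.001, 0.001, 0.001, 0.001),
                    padj = c(0.01, 0.01, 0.01, 0.01),
                    row.names = paste0("f", 1:4))
  calls <- callDifferential(tab, fdrMax = 0.05, lfcMin = 1)
  expect_equal(upCalls(calls), "f1")      # f2 at exactly 1.0 excluded
  expect_equal(downCalls(calls), "f3")

  # raw-p mode drops the fold-change floor
  pc <- callDifferential(tab, pMax = 0.05)
  expect_setequal(upCalls(pc), c("f1", "f2", "f4"))

  set.seed(13)
  big <- data.frame(log2FoldChange = rnorm(1000, sd = 1.5),
                    pvalue = runif(1000), padj = runif(1000),
                    row.names = paste0("f", 1:1000))
  got <- callDifferential(big, fdrMax = 0.05, lfcMin = 1)
  expect_setequal(upCalls(got), rownames(big)[big$padj < 0.05 &
                                                big$log2FoldChange > 1])
  expect_setequal(downCalls(got), rownames(big)[big$padj < 0.05 &
                                                  big$log2FoldChange < -1])
})

test_that("injected two-fold-change features are recovered with high sensitivity", {
  set.seed(17)
  nNull <- 1800; nTrue <- 200
  muNull <- matrix(100, nNull, 6)
  muTrue <- cbind(matrix(100, nTrue, 3), matrix(400, nTrue, 3))
  mu <- rbind(muNull, muTrue)
  m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05), nrow(mu))
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  groups <- rep(c("A", "B"), each = 3)
  tab <- nbDifferential(m, groups, c("A", "B"))
  calls <- callDifferential(tab, fdrMax = 0.05, lfcMin = 1)
  sens <- mean(rownames(m)[(nNull + 1):nrow(m)] %in% upCalls(calls))
  expect_gte(sens, 0.9)
})
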