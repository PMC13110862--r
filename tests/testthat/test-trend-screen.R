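# Williams trend screen: PAVA, the trend statistic, the permutation null
# and the fold-change prefilter.

test_that("PAVA reproduces the hand-worked amalgamation", {
  expect_equal(pavaMonotoneMeans(c(0, 1.0, 0.4, 0.8)),
               c(0, 0.7, 0.7, 0.8))
})

test_that("PAVA is a weighted isotonic projection with the expected
           fixed points", {
  expect_equal(pavaMonotoneMeans(c(1, 2, 3)), c(1, 2, 3))   # monotone input
  expect_equal(pavaMonotoneMeans(5), 5)                      # single group
  expect_error(pavaMonotoneMeans(numeric()), "non-empty")
  expect_error(pavaMonotoneMeans(c(1, 2), ns = c(1, 0)), "positive")
  # weights shift the pooled level toward the heavier group
  expect_equal(pavaMonotoneMeans(c(2, 0), ns = c(3, 1)), c(1.5, 1.5))
  # decreasing direction is the mirror image
  expect_equal(pavaMonotoneMeans(c(0.8, 0.4, 1.0, 0),
                                 direction = "decreasing"),
               rev(pavaMonotoneMeans(c(0, 1.0, 0.4, 0.8))))
})

test_that("PAVA properties hold on random cases: monotone, idempotent,
           mean-preserving, matches isoreg on equal weights", {
  withr::with_seed(99, {
    for (i in 1:25) {
      k <- sample(3:8, 1)
      y <- rnorm(k)
      w <- sample(1:5, k, replace = TRUE)
      fit <- pavaMonotoneMeans(y, w)
      expect_true(all(diff(fit) >= -1e-12))
      expect_equal(pavaMonotoneMeans(fit, w), fit)
      expect_equal(sum(w * fit), sum(w * y))
      # unweighted case: stats::isoreg is the independent oracle
      expect_equal(pavaMonotoneMeans(y), as.numeric(isoreg(y)$yf))
    }
  })
})

test_that("the Williams statistic matches the direct formula on clean
           group structure", {
  conc <- stdConc()
  # group means 0/0.5/1/1.5 with pooled within-group variance exactly 0.04
  off <- sqrt(0.06) * c(-1, 0, 0, 1)
  row <- rep(c(0, 0.5, 1, 1.5), each = 4) + rep(off, times = 4)
  ws <- williamsStatistic(row, conc)
  expect_equal(ws$tBar, 1.5 / sqrt(0.04 * (1 / 4 + 1 / 4)),
               tolerance = 1e-10)
  expect_equal(ws$pooledSd, 0.2, tolerance = 1e-10)
})

test_that("the Williams statistic is 0 on flat data, sign-symmetric and
           shift-invariant", {
  conc <- stdConc()
  expect_equal(williamsStatistic(rep(3, 16), conc)$tBar, 0)
  withr::with_seed(7, {
    for (i in 1:10) {
      row <- rnorm(16)
      t1 <- williamsStatistic(row, conc)$tBar
      expect_equal(abs(williamsStatistic(-row, conc)$tBar), abs(t1))
      expect_equal(williamsStatistic(row + 5, conc)$tBar, t1)
      expect_equal(abs(williamsStatistic(2 * row, conc)$tBar), abs(t1))
    }
  })
  expect_error(williamsStatistic(1:4, c(0, 0, 0, 0)), ">= 2")
  expect_error(williamsStatistic(1:4, c(0, 1, 2, 3)), "replicates")
})

test_that("permutation p-values respect the add-one bound and are
           deterministic under seed", {
  conc <- stdConc()
  row <- withr::with_seed(1, rnorm(16))
  p1 <- permutationPvalue(row, conc, B = 500, seed = 42)
  expect_identical(p1, permutationPvalue(row, conc, B = 500, seed = 42))
  expect_gte(p1, 1 / 501)
  # a responder at 20x the noise leaves no permutation above the observed
  strong <- rep(c(0, 2, 4, 6), each = 4) +
    withr::with_seed(2, rnorm(16, sd = 0.1))
  expect_equal(permutationPvalue(strong, conc, B = 500, seed = 1), 1 / 501)
})

test_that("screen defaults follow the published screening parameters", {
  expect_identical(formals(screenProbes)$alpha, 0.05)
  expect_identical(formals(screenProbes)$fcThreshold, 1.5)
  expect_identical(formals(screenProbes)$B, 500L)
})

test_that("screening an empty gene list yields an empty, well-formed
           result", {
  dre <- makeExperiment(matrix(numeric(), nrow = 0, ncol = 16))
  res <- screenProbes(dre, B = 50)
  expect_identical(nrow(res), 0L)
  expect_true(all(c("gene_id", "t_bar", "perm_p", "max_abs_log2fc",
                    "passes") %in% colnames(res)))
})

test_that("strong planted responders are recovered with high
           sensitivity", {
  d <- syntheticDesign(nGenes = 500, responderFraction = 0.1,
                       noiseSd = 0.15, seed = 77L)
  dre <- generateExpressionMatrix(d)
  res <- screenProbes(dre, B = 500, seed = 5)
  tr <- truthRecords(dre)
  expect_identical(sum(tr$is_responder), 50L)
  expect_gte(sum(res$passes & tr$is_responder), 45L)
  # the pass flag is exactly the conjunction the screen defines
  expect_identical(res$passes,
                   res$perm_p < 0.05 & res$max_abs_log2fc >= log2(1.5))
})
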