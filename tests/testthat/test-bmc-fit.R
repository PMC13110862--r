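# Model suite, BMC inversion, profile limits, model selection, filters and
# summaries.

test_that("model evaluation matches the standard forms", {
  expect_equal(evaluateModel("Hill", list(gamma = 8, v = 2, k = 100, n = 1),
                             100), 9)                       # half-maximal
  expect_equal(evaluateModel("Exp5", list(a = 7, b = 0.01, c = 1.5, g = 1),
                             0), 7)                          # intercept
  expect_equal(evaluateModel("Poly3", list(beta0 = 1, beta1 = 2, beta2 = 0,
                                           beta3 = 0), 3), 7)
  expect_equal(evaluateModel("Exp3", list(a = 2, b = 0.01, g = 1, s = 1),
                             100), 2 * exp(1))
  expect_error(evaluateModel("Hill", list(gamma = 0, v = 1, k = -5, n = 1),
                             1), "constraint")
  expect_error(evaluateModel("Frob", list(), 1), "unknown model")
})

test_that("noiseless linear data are recovered to machine precision", {
  d <- stdConc()
  fit <- fitModel("Linear", d, 8 + 0.004 * d)
  expect_true(converged(fit))
  expect_equal(unname(modelParams(fit)), c(8, 0.004), tolerance = 1e-10)
  # sigma is floored, so the BMC stays positive and finite
  expect_equal(sigmaHat(fit), 1e-6)
  expect_equal(bmcFromFit(fit), 1e-6 / 0.004, tolerance = 1e-6)
})

test_that("BMC inversion matches closed forms and drops flat fits", {
  d <- stdConc()
  mk <- function(modelId, params, sigma) {
    new("DoseResponseFit", modelId = modelId,
        params = unlist(params), sigmaHat = sigma, logLik = 0, aic = 0,
        converged = TRUE, doses = d, responses = numeric(length(d)))
  }
  expect_equal(bmcFromFit(mk("Linear", list(beta0 = 1, beta1 = 0.01), 0.25)),
               25)
  expect_equal(bmcFromFit(mk("Hill", list(gamma = 8, v = 2, k = 100, n = 1),
                             0.25)),
               100 * 0.125 / 0.875, tolerance = 1e-10)
  expect_true(is.na(bmcFromFit(mk("Linear", list(beta0 = 1, beta1 = 0),
                                  0.25))))
  # out-of-range BMC counts as absent
  expect_true(is.na(bmcFromFit(mk("Linear", list(beta0 = 1, beta1 = 1e-5),
                                  0.25))))
})

test_that("grid root-finding agrees with closed-form inversion", {
  d <- stdConc()
  cases <- list(
    list(model = "Hill", params = list(gamma = 8, v = -1.8, k = 60, n = 2),
         sigma = 0.2),
    list(model = "Hill", params = list(gamma = 5, v = 2.5, k = 300, n = 1.2),
         sigma = 0.3),
    list(model = "Linear", params = list(beta0 = 7, beta1 = 0.002),
         sigma = 0.25))
  for (cs in cases) {
    fit <- new("DoseResponseFit", modelId = cs$model,
               params = unlist(cs$params), sigmaHat = cs$sigma, logLik = 0,
               aic = 0, converged = TRUE, doses = d,
               responses = numeric(length(d)))
    closed <- bmcFromFit(fit)
    oracle <- gridSearchBMC(cs$model, cs$params, cs$sigma, 1000)
    expect_equal(closed, oracle, tolerance = 1e-3)
  }
})

test_that("profile limits bracket the BMC and tighten with replication", {
  params <- list(gamma = 8, v = 2, k = 100, n = 1.5)
  y4 <- simulateEndpoint("Hill", params, stdConc(4L), noiseSd = 0.2,
                         seed = 10)
  fit4 <- fitModel("Hill", stdConc(4L), y4)
  b4 <- bmcFromFit(fit4)
  ci4 <- profileCI(fit4)
  expect_lte(ci4$bmcl, b4)
  expect_gte(ci4$bmcu, b4)
  y32 <- simulateEndpoint("Hill", params, stdConc(32L), noiseSd = 0.2,
                          seed = 10)
  fit32 <- fitModel("Hill", stdConc(32L), y32)
  ci32 <- profileCI(fit32)
  expect_lt(ci32$bmcu / ci32$bmcl, ci4$bmcu / ci4$bmcl)
})

test_that("profile limits agree with a brute-force profile grid", {
  # independent oracle: for Linear the benchmark constraint pins
  # beta1 = s * sigma / b, leaving a 2-parameter profile evaluated on a
  # dense BMC grid
  d <- stdConc()
  y <- simulateEndpoint("Linear", list(beta0 = 8, beta1 = 0.0015), d,
                        noiseSd = 0.25, seed = 4)
  fit <- fitModel("Linear", d, y)
  bhat <- bmcFromFit(fit)
  ci <- profileCI(fit)
  n <- length(y)
  profNLL <- function(b) {
    nllSigma <- function(sigma) {
      beta1 <- sign(modelParams(fit)[["beta1"]]) * sigma / b
      beta0 <- mean(y - beta1 * d)
      sse <- sum((y - beta0 - beta1 * d)^2)
      n / 2 * log(2 * pi * sigma^2) + sse / (2 * sigma^2)
    }
    optimize(nllSigma, c(1e-4, 10))$objective
  }
  grid <- exp(seq(log(bhat / 50), log(bhat * 50), length.out = 400L))
  dev <- vapply(grid, function(b) 2 * (profNLL(b) + fit@logLik), numeric(1))
  thr <- qchisq(0.90, 1)
  crossing <- function(side) {
    idx <- if (side == "lower") which(grid < bhat) else which(grid > bhat)
    g <- grid[idx]; dv <- dev[idx]
    below <- dv < thr
    i <- if (side == "lower") min(which(below)) else max(which(below))
    j <- if (side == "lower") i - 1L else i + 1L
    approx(dv[c(i, j)], g[c(i, j)], xout = thr)$y
  }
  expect_equal(ci$bmcl, crossing("lower"), tolerance = 0.02)
  expect_equal(ci$bmcu, crossing("upper"), tolerance = 0.02)
})

test_that("model selection keeps the simplest adequate family member", {
  d <- stdConc()
  # single converged candidate wins by default
  y <- simulateEndpoint("Linear", list(beta0 = 8, beta1 = 0.002), d,
                        seed = 2)
  only <- fitAllModels(d, y, models = "Linear")
  expect_identical(modelId(selectBestModel(only)), "Linear")
  # under linear truth, Poly3 is rejected in the vast majority of runs
  keptLinear <- vapply(1:200, function(i) {
    yy <- simulateEndpoint("Linear", list(beta0 = 8, beta1 = 0.002), d,
                           noiseSd = 0.25, seed = 1000L + i)
    fits <- fitAllModels(d, yy, models = c("Linear", "Poly2", "Poly3"))
    modelId(selectBestModel(fits)) == "Linear"
  }, logical(1))
  expect_gte(mean(keptLinear), 0.9)
})

test_that("AIC ties break by parsimony then fixed order, ignoring
           non-converged candidates", {
  d <- stdConc()
  mk <- function(id, aic, conv = TRUE, npar = 2)
    new("DoseResponseFit", modelId = id, params = c(beta0 = 0),
        sigmaHat = 1, logLik = -aic / 2 + npar + 1, aic = aic,
        converged = conv, doses = d, responses = numeric(length(d)))
  # equal AIC: Hill (4 params) loses to Linear (2 params)
  fits <- list(Linear = mk("Linear", 10), Hill = mk("Hill", 10))
  expect_identical(modelId(selectBestModel(fits)), "Linear")
  # adding a non-converged candidate never changes the selection
  fits$Exp5 <- mk("Exp5", -100, conv = FALSE)
  expect_identical(modelId(selectBestModel(fits)), "Linear")
  expect_error(selectBestModel(list(bad = mk("Hill", 1, conv = FALSE))),
               "no converged fit")
})

test_that("reliability filters apply the range bound and the strict
           BMCU/BMCL ratio", {
  recs <- S4Vectors::DataFrame(
    endpoint_id = c("in_range", "too_high", "ratio_40", "wide", "nofit"),
    bmc = c(100, 1500, 100, 100, NA),
    bmcl = c(50, 700, 10, 5, NA),
    bmcu = c(200, 2900, 400, 900, NA),
    passes_filters = NA)
  out <- filterBMCRecords(recs, maxDose = 1000, ratioMax = 40)
  expect_identical(out$passes_filters,
                   c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(nrow(out), nrow(recs))
  # published defaults: range bound plus ratio < 40
  expect_identical(formals(filterBMCRecords)$ratioMax, 40)
})

test_that("BMC summaries reproduce the printed apical median and behave
           like percentile bootstraps", {
  # the two 6-week apical endpoints, reconstructed on the nM scale
  s <- summarizeBMCs(c(0.8417, 427.1))
  expect_equal(s$estimate, 214.0, tolerance = 2e-4)
  # single record: degenerate CI
  s1 <- summarizeBMCs(42)
  expect_identical(s1, list(estimate = 42, ciLow = 42, ciHigh = 42))
  # order invariance, CI containment, seed reproducibility
  v <- c(5, 80, 14, 2, 41, 7, 29)
  a <- summarizeBMCs(v, "p5", seed = 9)
  b <- summarizeBMCs(rev(v), "p5", seed = 9)
  expect_identical(a, b)
  expect_lte(a$ciLow, a$estimate)
  expect_gte(a$ciHigh, a$estimate)
  expect_error(summarizeBMCs(numeric()), "no records")
})
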