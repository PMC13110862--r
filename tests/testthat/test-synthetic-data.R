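# Synthetic-data generator: determinism, planted truth, analytic BMC oracle.

test_that("design validation rejects malformed inputs", {
  expect_error(syntheticDesign(concentrations = c(0, 100, 10)),
               "increasing")
  expect_error(syntheticDesign(concentrations = c(10, 100, 1000)),
               "include 0")
  expect_error(syntheticDesign(responderFraction = 1.2), "\\[0, 1\\]")
  expect_error(syntheticDesign(nReplicates = 1), ">= 2")
  # uM input is converted to nM at the boundary
  d <- syntheticDesign(concentrations = c(0, 0.01, 0.1, 1), units = "uM")
  expect_identical(d@concentrations, c(0, 10, 100, 1000))
})

test_that("generation is bit-identical under a fixed seed", {
  d <- syntheticDesign(nGenes = 30, responderFraction = 0.3, seed = 11L)
  m1 <- SummarizedExperiment::assay(generateExpressionMatrix(d))
  m2 <- SummarizedExperiment::assay(generateExpressionMatrix(d))
  expect_identical(m1, m2)
  d2 <- syntheticDesign(nGenes = 30, responderFraction = 0.3, seed = 12L)
  expect_false(identical(
    m1, SummarizedExperiment::assay(generateExpressionMatrix(d2))))
})

test_that("null design plants no responders and stays flat up to noise", {
  d <- syntheticDesign(nGenes = 80, responderFraction = 0, noiseSd = 0.2,
                       seed = 3L)
  dre <- generateExpressionMatrix(d)
  tr <- truthRecords(dre)
  expect_false(any(tr$is_responder))
  expect_true(all(is.na(tr$true_bmc)))
  # row means sit within a few SEs of the planted baseline
  base <- vapply(tr$params, function(p) p$beta0, numeric(1))
  dev <- rowMeans(SummarizedExperiment::assay(dre)) - base
  expect_true(all(abs(dev) < 5 * 0.2 / sqrt(16)))
})

test_that("non-responder row means converge to baseline with replication", {
  d <- syntheticDesign(nGenes = 40, responderFraction = 0,
                       nReplicates = 100L, noiseSd = 0.25, seed = 5L)
  dre <- generateExpressionMatrix(d)
  base <- vapply(truthRecords(dre)$params, function(p) p$beta0, numeric(1))
  dev <- rowMeans(SummarizedExperiment::assay(dre)) - base
  expect_true(all(abs(dev) < 5 * 0.25 / sqrt(400)))
})

test_that("trueBMC matches closed forms and handles absent responses", {
  # Linear: sigma / |beta1|
  rec <- list(is_responder = TRUE, model_id = "Linear",
              params = list(beta0 = 8, beta1 = -0.005))
  expect_equal(trueBMC(rec, noiseSd = 0.25), 0.25 / 0.005)
  # Hill hand inversion: k * x/(1-x) at n = 1, x = 0.25/2
  rec <- list(is_responder = TRUE, model_id = "Hill",
              params = list(gamma = 3, v = 2, k = 100, n = 1))
  expect_equal(trueBMC(rec, noiseSd = 0.25), 100 * 0.125 / 0.875,
               tolerance = 1e-12)
  # amplitude below the benchmark: unreachable
  rec$params$v <- 0.1
  expect_true(is.na(trueBMC(rec, noiseSd = 0.25)))
  # non-responders have no BMC
  expect_error(trueBMC(list(is_responder = FALSE), noiseSd = 0.25),
               "responder")
})

test_that("every planted true BMC agrees with the grid-search oracle", {
  d <- syntheticDesign(nGenes = 60, responderFraction = 0.5, seed = 21L,
                       responderModels = c("Hill", "Exp5", "Linear"))
  dre <- generateExpressionMatrix(d)
  tr <- truthRecords(dre)
  idx <- which(tr$is_responder & !is.na(tr$true_bmc))
  expect_gt(length(idx), 10)
  for (i in idx) {
    p <- tr$params[[i]]
    if (tr$model_id[i] == "Linear") p <- list(beta0 = p$beta0, beta1 = p$beta1)
    oracle <- gridSearchBMC(tr$model_id[i], p, target = d@noiseSd,
                            maxDose = 1000)
    expect_equal(tr$true_bmc[i], oracle, tolerance = 1e-3)
  }
})

test_that("planted Hill responders with bounded EC50 keep BMCs in range", {
  d <- syntheticDesign(nGenes = 100, responderFraction = 1, seed = 31L,
                       responderModels = "Hill",
                       amplitudeRange = c(2, 2), ec50Range = c(20, 500),
                       noiseSd = 0.25)
  tr <- truthRecords(generateExpressionMatrix(d))
  expect_true(all(tr$is_responder))
  expect_true(all(tr$true_bmc > 0 & tr$true_bmc < 1000))
})

test_that("apical tables are deterministic and screenable", {
  d <- syntheticDesign(seed = 41L)
  specs <- list(
    list(name = "flat_ep", model = "flat", params = list(baseline = 50),
         noiseSd = 1),
    list(name = "monotone_ep", model = "Hill",
         params = list(gamma = 10, v = 8, k = 100, n = 1.5), noiseSd = 0.3))
  t1 <- generateApicalTable(d, specs)
  t2 <- generateApicalTable(d, specs)
  expect_identical(t1, t2)
  expect_false(identical(
    t1, generateApicalTable(syntheticDesign(seed = 42L), specs)))
  expect_error(generateApicalTable(d, list()), "at least one")
  # flat endpoint: group means equal within noise
  flat <- t1[t1$endpoint == "flat_ep", ]
  gm <- tapply(flat$value, flat$concentration_nM, mean)
  expect_true(all(abs(gm - 50) < 5 * 1 / sqrt(4)))
  # the monotone endpoint survives the trend screen, the flat one does not
  dre <- apicalToExperiment(t1)
  res <- screenProbes(dre, B = 200, seed = 1)
  expect_true(res["monotone_ep", "passes"])
  expect_false(res["flat_ep", "passes"])
})

test_that("printed fixture carries the published constants", {
  fx <- printedValuesFixture()
  expect_equal(fx$ART_ref_median, 3.5)
  expect_equal(unname(fx$occupational_ref), c(303.6, 877.3, 13942.7))
  expect_equal(fx$fu_plasma, 0.0033)
  expect_equal(fx$bfte, 0.75)
  f <- withr::local_tempfile(fileext = ".json")
  printedValuesFixture(f)
  expect_equal(jsonlite::read_json(f)$ART_ref_median, 3.5)
})

test_that("expression matrices round-trip through the TSV dialect", {
  dre <- generateExpressionMatrix(
    syntheticDesign(nGenes = 12, responderFraction = 0.5, seed = 8L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(dre, f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr[1:2], c("gene_id", "conc_0_rep1"))
  back <- readExpressionMatrix(f)
  expect_equal(concentrations(back), concentrations(dre))
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(dre), tolerance = 1e-6)
  ft <- withr::local_tempfile(fileext = ".tsv")
  writeTruthTable(dre, ft)
  tt <- read.delim(ft)
  expect_equal(sum(tt$is_responder), 6)
})
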