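# Unit bridge, HED conversion, reference exposures, BERs and pathway
# aggregation.

test_that("nM <-> ng/ml conversion is exact and invertible", {
  expect_equal(nMToNgPerMl(0), 0)
  expect_equal(nMToNgPerMl(1000), 500.13)
  expect_equal(nMToNgPerMl(38.1), 19.055, tolerance = 1e-4)
  withr::with_seed(3, {
    x <- runif(20, 0, 2000)
    expect_equal(ngPerMlToNM(nMToNgPerMl(x)), x, tolerance = 1e-14)
  })
  expect_error(nMToNgPerMl(-1), ">= 0")
})

test_that("the BMC -> HED conversion reproduces the printed endpoints", {
  expect_equal(bmcToHED(38.1), 18.1, tolerance = 5e-3)
  # apical extremes, reconstructed by exact inversion
  expect_equal(bmcToHED(427.1331), 203, tolerance = 1e-4)
  expect_equal(bmcToHED(0.8416416), 0.4, tolerance = 1e-4)
  # hedToBMC is the exact inverse
  expect_equal(hedToBMC(bmcToHED(38.1)), 38.1, tolerance = 1e-12)
  # the potassium-salt MW breaks the printed chain (sensitivity)
  expect_gt(abs(bmcToHED(38.1, mw = MW_PFOS_K) - 18.1), 0.1)
})

test_that("the printed chain closes through the apical median", {
  heds <- c(0.4, 203)
  backNM <- hedToBMC(heds)
  expect_equal(summarizeBMCs(backNM)$estimate, 214, tolerance = 5e-3)
})

test_that("reference exposures are built from HEDs or serum x BFTE", {
  art <- artReference()
  expect_equal(unname(referenceHEDs(art)), c(0.1, 3.5, 172))
  occ <- occupationalReference()
  expect_equal(unname(referenceHEDs(occ)), c(303.6, 877.3, 13943.4),
               tolerance = 1e-3)
  expect_equal(unname(occ@conc), c(426, 1231, 19564) * 0.75)
  expect_equal(referenceHEDs(occupationalReference(serum = c(0, 0, 0)))[[1]],
               0)
  expect_error(occupationalReference(bfte = 1.2), "\\(0, 1\\]")
  # ART can also be rebuilt from follicular-fluid concentrations
  art2 <- artReference(conc = c(0.1, 4, 181))
  expect_equal(referenceHEDs(art2)[["max"]], 172, tolerance = 1e-12)
})

test_that("BERs divide bioactive by reference HEDs with one-decimal
           reporting", {
  expect_equal(berReport(ber(1.4, 3.5)), 0.4)
  expect_equal(berReport(ber(2.8, 3.5)), 0.8)
  expect_equal(berReport(ber(0.4, 3.5)), 0.1)
  expect_equal(ber(7, 7), 1)
  expect_error(ber(1, 0), "> 0")
})

test_that("BER intervals are ordered and flag occupational exceedance", {
  occ <- occupationalReference()
  rec <- berInterval(17.5, occ, "hed_median_12wk")
  expect_lte(rec$ber_at_max_ref, rec$ber_at_median_ref)
  expect_lte(rec$ber_at_median_ref, rec$ber_at_min_ref)
  expect_true(rec$below_one_min)   # whole interval below 1
  # every uncorrected endpoint HED sits below the occupational minimum
  heds <- c(18.1, 17.5, 17.3, 101.7, 2.8, 24.1, 0.4, 203)
  expect_true(all(ber(heds, referenceHEDs(occ)[["min"]]) < 1))
  art <- artReference()
  expect_false(berInterval(17.5, art)$below_one_median)
  expect_true(berInterval(1.4, art)$below_one_median)
})

test_that("low-BER gene flagging equals the brute-force filter, sorted by
           risk", {
  withr::with_seed(12, {
    heds <- setNames(rexp(60, rate = 1 / 10), paste0("g", 1:60))
  })
  refHed <- 3.5
  flagged <- flagLowBERGenes(heds, refHed)
  brute <- names(heds)[heds / refHed < 1]
  expect_setequal(flagged, brute)
  expect_false(is.unsorted(heds[flagged] / refHed))
  expect_identical(flagLowBERGenes(setNames(numeric(), character()), 1),
                   character())
  expect_identical(flagLowBERGenes(c(hit = 1.7), 3.5), "hit")
})

test_that("pathway HEDs aggregate member-gene medians", {
  heds <- c(a = 2.0, b = 3.6, c = 9, d = 1)
  expect_equal(aggregatePathwayHED(heds, c("a", "b")), 2.8)   # mean of two
  expect_equal(aggregatePathwayHED(heds, "c"), 9)             # singleton
  expect_equal(aggregatePathwayHED(heds, c("b", "a", "zzz")),
               aggregatePathwayHED(heds, c("a", "b")))        # order/overlap
  expect_true(is.na(aggregatePathwayHED(heds, "absent")))
  # GMT round trip
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\ta\tb", "setB\tdesc\tc\td"), f)
  sets <- readGeneSets(f)
  expect_equal(aggregatePathwayHED(heds, sets$setA), 2.8)
})

test_that("HED summaries mirror BMC summaries through the monotone
           conversion", {
  v <- c(5, 80, 14, 2, 41)
  expect_equal(summarizeHEDs(bmcToHED(v))$estimate,
               bmcToHED(summarizeBMCs(v)$estimate), tolerance = 1e-12)
  s1 <- summarizeHEDs(v, "p5", seed = 7)
  expect_identical(s1, summarizeHEDs(v, "p5", seed = 7))
  const <- summarizeHEDs(rep(3, 5))
  expect_equal(const$ciLow, 3); expect_equal(const$ciHigh, 3)
})

test_that("the whole chain is scale-equivariant in the BMC", {
  bmcs <- c(5, 38.1, 400)
  f <- 16.685
  hed1 <- bmcToHED(bmcs)
  hed2 <- bmcToHED(bmcs * f)
  expect_equal(hed2, hed1 * f, tolerance = 1e-12)
  expect_equal(ber(hed2, 3.5), ber(hed1, 3.5) * f, tolerance = 1e-12)
})

test_that("reference tables round-trip through TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("population\tstatistic\thed\tserum_ng_ml",
               "ART\tmin\t0.1\tNA", "ART\tmedian\t3.5\tNA",
               "ART\tmax\t172\tNA",
               "occupational\tmin\tNA\t426",
               "occupational\tmedian\tNA\t1231",
               "occupational\tmax\tNA\t19564"), f)
  refs <- readReferenceTable(f)
  expect_equal(unname(referenceHEDs(refs$ART)), c(0.1, 3.5, 172))
  expect_equal(referenceHEDs(refs$occupational)[["median"]], 877.3,
               tolerance = 1e-3)
})
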