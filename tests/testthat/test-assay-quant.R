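test_that("percent formulas hit their endpoint and midpoint identities", {
  expect_equal(hemolysisPercent(0.1, 0.1, 0.9), 0)
  expect_equal(hemolysisPercent(0.9, 0.1, 0.9), 100)
  expect_equal(hemolysisPercent(0.5, 0.1, 0.9), 50)
  expect_equal(ldhReleasePercent(0.2, 0.2, 0.6), 0)
  expect_equal(ldhReleasePercent(0.6, 0.2, 0.6), 100)
  expect_equal(ldhReleasePercent(0.3, 0.2, 0.6), 25)
  expect_equal(mttViabilityPercent(1.0, 1.0, 0.1), 100)
  expect_equal(mttViabilityPercent(0.1, 1.0, 0.1), 0)
  expect_equal(mttViabilityPercent(0.55, 1.0, 0.1), 50)
})

test_that("degenerate controls raise errors, out-of-range values are flagged not clipped", {
  expect_error(hemolysisPercent(0.5, 0.9, 0.9), "degenerate")
  expect_error(ldhReleasePercent(0.5, 0.7, 0.6), "degenerate")
  expect_error(mttViabilityPercent(0.5, 0.1, 0.1), "degenerate")
  p <- hemolysisPercent(1.2, 0.1, 0.9)
  expect_gt(p, 100)
  expect_true(outOfRange(p))
  expect_false(outOfRange(50))
})

test_that("percent formulas are invariant under affine OD transforms", {
  for (lo in c(0.05, 0.2)) for (hi in c(0.6, 1.4)) for (od in c(0.1, 0.45, 1.0)) {
    base <- hemolysisPercent(od, lo, hi)
    for (shift in c(0.02, 0.3)) for (scale in c(0.5, 2.5)) {
      expect_equal(hemolysisPercent(scale * od + shift, scale * lo + shift,
                                    scale * hi + shift), base,
                   tolerance = 1e-9)
      expect_equal(ldhReleasePercent(scale * od + shift, scale * lo + shift,
                                     scale * hi + shift), base,
                   tolerance = 1e-9)
      expect_equal(mttViabilityPercent(scale * od + shift, scale * hi + shift,
                                       scale * lo + shift), base,
                   tolerance = 1e-9)
    }
  }
})

test_that("a noiseless 4PL curve is recovered at its planted midpoint", {
  d <- genDoseResponse(ic50 = 3.39, hill = 2, top = 100, bottom = 0,
                       doses = 10^seq(-1, 1.2, length.out = 8),
                       noise_sd = 0, replicates = 1, seed = 1)
  f <- fitDoseResponse(d)
  expect_true(f@converged)
  expect_equal(f@ic50, 3.39, tolerance = 0.01 / 3.39)
  expect_equal(f@ic50Absolute, 3.39, tolerance = 0.01)  # symmetric curve
  expect_equal(f@top, 100, tolerance = 0.01)
  expect_equal(f@hill, 2, tolerance = 0.01)
  expect_false(f@censored)
})

test_that("a symmetric step recovers the middle dose as midpoint", {
  doses <- 10^(0:4)
  d <- doseResponseDataset(doses, c(100, 100, 50, 0, 0))
  f <- fitDoseResponse(d)
  expect_equal(f@ic50, 100, tolerance = 1e-3)
})

test_that("flat and wrong-direction responses are refused honestly", {
  d <- doseResponseDataset(10^(0:4), rep(100, 5))
  expect_error(fitDoseResponse(d), "no dose-response signal")
  up <- doseResponseDataset(10^(0:4), c(10, 30, 50, 80, 100))
  expect_warning(f <- fitDoseResponse(up), "wrong direction")
  expect_false(f@converged)
  expect_true(is.na(f@ic50))
})

test_that("the fit is equivariant under a dose-unit change", {
  d <- genDoseResponse(ic50 = 4, hill = 1.5, noise_sd = 3, seed = 9)
  f1 <- fitDoseResponse(d)
  d2 <- d; d2$concentration <- d2$concentration * 1000  # uM -> nM
  f2 <- fitDoseResponse(d2)
  expect_equal(f2@ic50 / f1@ic50, 1000, tolerance = 1e-6)
})

test_that("midpoints beyond the tested range are censored like 'ND (>10)'", {
  d <- genDoseResponse(ic50 = 15, hill = 2, doses = c(0.6, 1.25, 2.5, 5, 10),
                       noise_sd = 0, replicates = 1, seed = 2, bottom = 0)
  f <- fitDoseResponse(d, min_span = 20)
  expect_true(f@censored)
  expect_equal(f@label, "> 10")
})

test_that("IC50 recovery under noise is accurate in the median", {
  set.seed(1234)
  relErr <- vapply(1:25, function(s) {
    ic50 <- 10^runif(1, log10(0.5), log10(50))
    hill <- runif(1, 0.5, 4)
    d <- genDoseResponse(ic50 = ic50, hill = hill, top = 100, bottom = 0,
                         doses = 10^seq(-1, 2, length.out = 8),
                         noise_sd = 5, replicates = 3, seed = s)
    f <- fitDoseResponse(d, max_dose = Inf)
    abs(f@ic50 - ic50) / ic50
  }, numeric(1))
  expect_lt(median(relErr), 0.10)
})

test_that("HC50 fitting reports the half-hemolysis dose or a censored bound", {
  doses <- 10^seq(0, 2.7, length.out = 8)
  d <- genDoseResponse(ic50 = 100, hill = -2, top = 100, bottom = 0,
                       doses = doses, noise_sd = 0, replicates = 1, seed = 3)
  f <- hc50(d)
  expect_equal(f@ic50, 100, tolerance = 0.5 / 100)
  flat <- doseResponseDataset(c(1.25, 2.5, 5, 10), c(2, 3, 4, 6))
  f2 <- hc50(flat)
  expect_true(f2@censored)
  expect_equal(f2@label, "> 10")
})

test_that("selectivity index divides and propagates censoring as a bound", {
  si <- selectivityIndex(100, 3.39)
  expect_equal(si$value, 29.5, tolerance = 0.002)
  expect_false(si$censored)
  expect_equal(selectivityIndex(5, 5)$value, 1.0)
  cb <- selectivityIndex("> 10", 5)
  expect_true(cb$censored)
  expect_equal(cb$value, 2.0)
  expect_equal(cb$label, "> 2")
  expect_error(selectivityIndex(10, "> 5"), "no usable bound")
})
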