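# Synthetic cohort generator.

test_that("exvivo preset yields 48 thrombi and 188 slices with 44x4+4x3 allocation", {
  coh <- exvivoCohort()
  expect_equal(nThrombi(coh), 48L)
  expect_equal(nSlices(coh), 188L)
  counts <- thrombusData(coh)$nSlices
  expect_equal(sum(counts == 4L), 44L)
  expect_equal(sum(counts == 3L), 4L)
})

test_that("minimal one-thrombus one-slice cohort is valid", {
  coh <- generateCohort(GeneratorConfig(nThrombi = 1L, totalSlices = 1L,
                                        seed = 3L))
  expect_equal(nThrombi(coh), 1L)
  expect_equal(nSlices(coh), 1L)
  expect_true(validObject(coh))
})

test_that("identical config and seed reproduce the cohort field by field", {
  cfg <- GeneratorConfig(nThrombi = 4L, totalSlices = 9L, seed = 21L)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(thrombusData(a), thrombusData(b))
  for (i in seq_len(nSlices(a))) {
    expect_identical(slices(a)[[i]]@channels, slices(b)[[i]]@channels)
    expect_identical(slices(a)[[i]]@mask, slices(b)[[i]]@mask)
  }
})

test_that("invalid generator configurations name the offending field", {
  expect_error(GeneratorConfig(nThrombi = 0L), "nThrombi")
  expect_error(GeneratorConfig(nThrombi = 5L, totalSlices = 3L),
               "totalSlices")
  expect_error(GeneratorConfig(rbcQuantiles = c(12, 30, 30, 49, 61)),
               "rbcQuantiles")
  expect_error(GeneratorConfig(teLate = 0), "teLate")
  expect_error(GeneratorConfig(sliceAllocation = "alphabetical"),
               "sliceAllocation")
})

test_that("RBC quantile anchors bound every generated thrombus", {
  coh <- smallCohort()
  q <- coh@config@rbcQuantiles
  rbc <- thrombusData(coh)$rbcPercent
  expect_true(all(rbc >= q[1L] & rbc <= q[5L]))
})

test_that("channels are exactly zero outside the mask and GRE is nonnegative", {
  for (s in slices(smallCohort())[1:6]) {
    out <- s@mask == 0
    for (k in 1:3) expect_true(all(s@channels[, , k][out] == 0))
    expect_true(all(s@channels[, , 3L] >= 0))
  }
})

test_that("noiseless GRE equals m0 exp(-teLate R2*) inside the mask", {
  cfg <- GeneratorConfig(nThrombi = 1L, totalSlices = 1L,
                         noiseSd = c(r2star = 0, qsm = 0, gre = 0),
                         seed = 5L)
  s <- slices(generateCohort(cfg))[[1L]]
  m <- s@mask == 1
  m0 <- cfg@calibration[["m0"]]
  expect_equal(s@channels[, , "gre"][m],
               m0 * exp(-cfg@teLate * s@channels[, , "r2star"][m]),
               tolerance = 1e-12)
})

test_that("rbcPercent = 0 renders a patch-free slice at the low calibration value", {
  cfg <- GeneratorConfig(nThrombi = 1L, totalSlices = 1L,
                         noiseSd = c(r2star = 0, qsm = 0, gre = 0), seed = 2L)
  s <- renderSlice("T0001", 1L, rbcPercent = 0, oxygenation = 1,
                   config = cfg, seed = 7L)
  m <- s@mask == 1
  expect_true(all(s@channels[, , "r2star"][m] == cfg@calibration[["r2sLow"]]))
  expect_true(all(s@channels[, , "qsm"][m] == cfg@calibration[["qsmLow"]]))
})

test_that("noiseless patch area fraction recovers the RBC target (identifiability)", {
  cfg <- GeneratorConfig(nThrombi = 1L, totalSlices = 1L,
                         noiseSd = c(r2star = 0, qsm = 0, gre = 0), seed = 2L)
  hi <- cfg@calibration[["r2sHigh"]]; lo <- cfg@calibration[["r2sLow"]]
  for (rbc in c(10, 38, 50, 85)) {
    for (seed in c(11L, 12L)) {
      oxy <- 1.3
      s <- renderSlice("T0001", 1L, rbc, oxy, cfg, seed)
      m <- s@mask == 1
      # brute-force patch count: pixels at the high amplitude
      frac <- mean(abs(s@channels[, , "r2star"][m] - hi * oxy) <
                     abs(s@channels[, , "r2star"][m] - lo))
      expect_lt(abs(frac * 100 - rbc), 2 + 100 / sum(m))
    }
  }
})

test_that("cohort summary flags undefined correlation for a single thrombus", {
  coh <- generateCohort(GeneratorConfig(nThrombi = 1L, totalSlices = 2L,
                                        seed = 9L))
  s <- cohortSummary(coh)
  expect_false(s$correlationDefined)
  expect_true(is.na(s$rR2s))
  expect_equal(unname(s$rbc["median"]), unname(s$rbc["min"]))
  expect_equal(unname(s$rbc["median"]), unname(s$rbc["max"]))
})

test_that("with the oxygenation confounder off, mean R2* tracks RBC almost perfectly", {
  cfg <- GeneratorConfig(nThrombi = 200L, totalSlices = 200L,
                         oxygenationSd = 0,
                         noiseSd = c(r2star = 0, qsm = 0, gre = 0),
                         seed = 31L)
  s <- cohortSummary(generateCohort(cfg))
  # brute-force check is the summary's own Pearson r on the simulation
  expect_gt(s$rR2s, 0.99)
})

test_that("slice index out of range is rejected by the cohort contract", {
  coh <- smallCohort()
  idx <- vapply(slices(coh), function(s) s@sliceIndex, 0L)
  counts <- thrombusData(coh)$nSlices
  expect_true(all(idx >= 1L))
  expect_true(all(idx <= max(counts)))
})

test_that("poisson-adjusted allocation still hits the exact slice total", {
  cfg <- GeneratorConfig(nThrombi = 12L, totalSlices = 50L,
                         sliceAllocation = "poisson-adjusted", seed = 17L)
  coh <- generateCohort(cfg)
  expect_equal(nSlices(coh), 50L)
  expect_true(all(thrombusData(coh)$nSlices >= 1L))
})
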