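test_that("TSV recordings round-trip exactly", {
  set.seed(1)
  rec <- mkRecording(matrix(rnorm(3 * 200), 3), fs = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRecordingTSV(rec, f)
  back <- readRecording(f, "tsv", fs = 50)
  expect_equal(signalMatrix(back), signalMatrix(rec))
  expect_identical(channelLabels(back), channelLabels(rec))
  expect_error(readRecording(f, "tsv"), "fs")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(readRecording(empty, "tsv", fs = 50))
})

test_that("EDF round-trips within 16-bit quantization error", {
  set.seed(2)
  rec <- mkRecording(matrix(rnorm(2 * 640, sd = 40), 2), fs = 64)
  f <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, f)
  back <- readEDF(f)
  expect_equal(samplingRate(back), 64)
  expect_identical(channelLabels(back), channelLabels(rec))
  bound <- max(apply(abs(signalMatrix(rec)), 1, max)) / 32767
  expect_lt(max(abs(signalMatrix(back) - signalMatrix(rec))), bound)
  expect_error(writeEDF(mkRecording(matrix(0.0, 1, 10), fs = 12.5), f),
               "integer sampling rate")
})

test_that("artifact masking follows half-open interval arithmetic", {
  set.seed(3)
  rec <- mkRecording(matrix(rnorm(2 * 5000), 2), fs = 100)
  expect_identical(retainedMask(applyArtifactMask(rec, NULL)),
                   retainedMask(rec))
  masked <- applyArtifactMask(rec, rbind(c(10, 20)))
  expect_equal(sum(!retainedMask(masked)), 1000)
  expect_true(all(which(!retainedMask(masked)) == 1001:2000))
  expect_error(applyArtifactMask(rec, rbind(c(20, 10))), "end must exceed")
  expect_error(applyArtifactMask(rec, rbind(c(40, 60))), "span")
})

test_that("masking everything yields an empty catalog downstream", {
  rec <- randomZRec(2, 3000, seed = 4)
  rec@mask <- rep(FALSE, nSamples(rec))
  raster <- detectExcursions(rec, 2)
  expect_equal(sum(raster@beyond), 0)
  expect_equal(nAvalanches(extractAvalanches(raster, rec)), 0)
})

test_that("z-scoring is affine-invariant, idempotent and guards variance", {
  set.seed(5)
  x <- matrix(rnorm(2 * 1000), 2)
  z1 <- signalMatrix(zscoreNormalize(mkRecording(x)))
  z2 <- signalMatrix(zscoreNormalize(mkRecording(3.7 * x + 11)))
  expect_equal(z1, z2, tolerance = 1e-12)
  zz <- signalMatrix(zscoreNormalize(zscoreNormalize(mkRecording(x))))
  expect_equal(z1, zz, tolerance = 1e-12)
  ## already-standardized channels are unchanged
  xs <- (x - rowMeans(x)) / apply(x, 1, sd)
  expect_equal(signalMatrix(zscoreNormalize(mkRecording(xs))), xs,
               tolerance = 1e-9)
  bad <- mkRecording(rbind(x[1, ], rep(2, 1000)))
  expect_error(zscoreNormalize(bad), "ch02")
})

test_that("z-score moments are computed over retained samples only", {
  set.seed(6)
  rec <- mkRecording(matrix(rnorm(2 * 4000), 2), fs = 100)
  rec@signal[, 1001:2000] <- rec@signal[, 1001:2000] + 50  # artifact block
  masked <- applyArtifactMask(rec, rbind(c(10, 20)))
  z <- zscoreNormalize(masked)
  kept <- signalMatrix(z)[, retainedMask(z)]
  expect_equal(unname(rowMeans(kept)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(kept, 1, sd)), c(1, 1), tolerance = 1e-6)
  ## equals the statistics of the recording with masked samples deleted
  del <- mkRecording(rec@signal[, -(1001:2000)], fs = 100)
  expect_equal(kept, signalMatrix(zscoreNormalize(del)), tolerance = 1e-12)
})

test_that("excursion detection uses a strict threshold and honors the mask", {
  sig <- rbind(c(0, 2, -2, 0, 2.5, -2.5, 0, 0))  # mean exactly 0
  rec <- new("MultichannelRecording", signal = sig, fs = 100,
             channelLabels = "ch01", mask = rep(TRUE, 8), t0 = 0,
             zscored = TRUE)
  raster <- detectExcursions(rec, 2)
  expect_identical(which(raster@beyond[1, ]), c(5L, 6L))  # exactly 2 excluded
  expect_error(detectExcursions(mkRecording(sig), 2), "z-scored")
  zeroRec <- mkZRecording(matrix(0, 2, 50))
  expect_equal(sum(detectExcursions(zeroRec, 2)@beyond), 0)
  ## masked samples can never be excursions
  rec2 <- randomZRec(2, 500, seed = 7)
  rec2@mask[100:200] <- FALSE
  r2 <- detectExcursions(rec2, 1)
  expect_true(all(!r2@beyond[, 100:200]))
})

test_that("excursion raster equals a brute-force scan and is monotone in theta", {
  rec <- randomZRec(4, 1500, seed = 8)
  prev <- NULL
  for (theta in c(0.5, 1, 2, 3)) {
    raster <- detectExcursions(rec, theta)
    brute <- abs(signalMatrix(rec)) > theta
    expect_identical(raster@beyond, brute)
    if (!is.null(prev)) expect_true(all(raster@beyond <= prev))
    prev <- raster@beyond
  }
})

test_that("gaussianity report flags burst-laden signals near 2 SD", {
  set.seed(9)
  nullRec <- zscoreNormalize(mkRecording(matrix(rnorm(1e6), 4)))
  repNull <- gaussianityReport(nullRec, tolerance = 0.25)
  expect_gt(repNull$deviationOnsetSD, 3)
  expect_lt(abs(repNull$gaussianFit[["sd"]] - 1), 0.05)

  arch <- architectureConfig(nCycles = 1L)
  hyp <- simulateHypnogram(arch, seed = 7)
  cap <- simulateCapAnnotations(hyp, arch, seed = 8)
  sur <- synthesizeRecording(hyp, cap, couplingConfig(burstAmplitude = 3),
                             nChannels = 8L, fs = 128, seed = 9)
  repBurst <- gaussianityReport(zscoreNormalize(sur$recording),
                                tolerance = 0.25)
  expect_gt(repBurst$deviationOnsetSD, 1.5)
  expect_lt(repBurst$deviationOnsetSD, 3)

  expect_identical(gaussianityReport(nullRec, tolerance = Inf)$deviationOnsetSD,
                   Inf)
  tiny <- zscoreNormalize(mkRecording(matrix(rnorm(2000), 2)))
  expect_error(gaussianityReport(tiny), "1e4")
})
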