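## A rectangular |z| = 3 pulse of known length, recentred so the channel has
## exactly zero mean: 50 pulse samples at +3 and 50 at -3, far apart.
rectPulseRec <- function() {
  sig <- matrix(0, 1, 1000)
  sig[1, 101:150] <- 3
  sig[1, 601:650] <- -3
  new("MultichannelRecording", signal = sig, fs = 100,
      channelLabels = "ch01", mask = rep(TRUE, 1000), t0 = 0, zscored = TRUE)
}

test_that("a rectangular pulse yields the forced size and duration", {
  rec <- rectPulseRec()
  raster <- detectExcursions(rec, 2)
  cat <- extractAvalanches(raster, rec)
  expect_equal(nAvalanches(cat), 2)
  av <- avalanches(cat)
  expect_equal(av$duration_s, c(0.5, 0.5))
  expect_equal(av$size, c(1.5, 1.5))            # 3 SD x 0.5 s
  expect_equal(av$n_channels, c(1L, 1L))
  ## sample_sum mode drops the 1/fs factor
  cat2 <- extractAvalanches(raster, rec, sizeMode = "sample_sum")
  expect_equal(avalanches(cat2)$size, c(150, 150))
})

test_that("extraction matches a brute-force scan on random rasters", {
  for (seed in 1:4) {
    rec <- randomZRec(3, 1200, seed = seed)
    if (seed %% 2 == 0) rec@mask[300:400] <- FALSE
    raster <- detectExcursions(rec, 1.5)
    cat <- extractAvalanches(raster, rec)
    ref <- bruteForceAvalanches(raster, rec)
    av <- avalanches(cat)
    expect_equal(av$onset_sample, unname(ref[, "start"]))
    expect_equal(av$offset_sample, unname(ref[, "end"]) + 1L)
    expect_equal(av$size, unname(ref[, "size"]))
    expect_equal(av$n_channels, as.integer(ref[, "n_channels"]))
  }
})

test_that("avalanche intervals cover exactly the retained excursion samples", {
  rec <- randomZRec(3, 3000, seed = 5)
  rec@mask[1000:1100] <- FALSE
  raster <- detectExcursions(rec, 1.5)
  cat <- extractAvalanches(raster, rec)
  av <- avalanches(cat)
  covered <- logical(nSamples(rec))
  for (i in seq_len(nrow(av)))
    covered[av$onset_sample[i]:(av$offset_sample[i] - 1L)] <- TRUE
  active <- colSums(raster@beyond) > 0
  ## coverage equals active samples except runs dropped at mask boundaries
  runs <- rle(active)
  expect_true(all(active[covered]))
  ## every avalanche sample has at least one channel beyond threshold
  expect_true(all(active[covered]))
  ## integrated size is at least theta * T
  expect_true(all(av$size >= raster@theta * av$duration_s - 1e-9))
})

test_that("catalogs are invariant under channel permutation", {
  rec <- randomZRec(4, 1500, seed = 6)
  raster <- detectExcursions(rec, 1.5)
  cat1 <- extractAvalanches(raster, rec)
  perm <- c(3, 1, 4, 2)
  rec2 <- rec
  rec2@signal <- rec@signal[perm, ]
  rec2@channelLabels <- rec@channelLabels[perm]
  cat2 <- extractAvalanches(detectExcursions(rec2, 1.5), rec2)
  expect_equal(avalanches(cat1), avalanches(cat2))
})

test_that("total avalanche time is non-increasing in theta", {
  rec <- randomZRec(3, 4000, seed = 7)
  times <- vapply(c(1, 1.5, 2, 2.5), function(theta) {
    sum(avalancheDurations(extractAvalanches(detectExcursions(rec, theta),
                                             rec)))
  }, numeric(1))
  expect_true(all(diff(times) <= 0))
})

test_that("raster branching estimator reproduces a forced ratio", {
  ## single avalanche spanning two 4-sample bins: 2 channel events start in
  ## bin 1, 4 in bin 2
  B <- matrix(FALSE, 6, 100)
  B[1, 2:9] <- TRUE            # starts bin 1
  B[2, 3:5] <- TRUE            # starts bin 1
  B[3, 6:7] <- TRUE            # starts bin 2
  B[4, 6:9] <- TRUE            # starts bin 2
  B[5, 7:8] <- TRUE            # starts bin 2
  B[6, 8:9] <- TRUE            # starts bin 2
  sig <- matrix(0, 6, 100)
  sig[B] <- 3
  sig <- sig - rowMeans(sig)   # small offset; on-samples stay above 2 SD
  rec <- new("MultichannelRecording", signal = sig, fs = 100,
             channelLabels = sprintf("ch%02d", 1:6), mask = rep(TRUE, 100),
             t0 = 0, zscored = TRUE)
  raster <- detectExcursions(rec, 2)
  cat <- extractAvalanches(raster, rec)
  expect_equal(nAvalanches(cat), 1)
  est <- estimateBranchingParameter(cat, raster, binWidth = 4 / 100)
  expect_equal(est$sigmaHat, 2.0)
  expect_equal(est$nAvalanchesUsed, 1L)
})

test_that("branching estimation fails when no avalanche spans two bins", {
  rec <- rectPulseRec()
  raster <- detectExcursions(rec, 2)
  cat <- extractAvalanches(raster, rec)
  expect_error(estimateBranchingParameter(cat, raster, binWidth = 1),
               "two bins")
})

test_that("interval filtering keeps avalanches by onset", {
  rec <- rectPulseRec()
  raster <- detectExcursions(rec, 2)
  cat <- extractAvalanches(raster, rec)
  whole <- filterCatalogByIntervals(cat, rbind(c(0, 10)))
  expect_equal(avalanches(whole), avalanches(cat))
  expect_equal(whole@totalRetainedTime, 10)
  none <- filterCatalogByIntervals(cat, rbind(c(3, 5)))
  expect_equal(nAvalanches(none), 0)
  expect_error(filterCatalogByIntervals(cat, NULL), "empty")
  ## toy onsets {1, 5, 9} s against [4, 10)
  toy <- cat
  toy@avalanches <- data.frame(
    onset_sample = c(101L, 501L, 901L), offset_sample = c(111L, 511L, 911L),
    onset_s = c(1, 5, 9), offset_s = c(1.1, 5.1, 9.1),
    duration_s = rep(0.1, 3), size = rep(1, 3), n_channels = rep(1L, 3))
  kept <- filterCatalogByIntervals(toy, rbind(c(4, 10)))
  expect_equal(avalanches(kept)$onset_s, c(5, 9))
  expect_equal(kept@totalRetainedTime, 6)
})
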