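test_that("sliding density equals brute-force window summation", {
  rec <- randomZRec(3, 3000, seed = 21)
  rec@mask[700:900] <- FALSE
  raster <- detectExcursions(rec, 1.5)
  cat <- extractAvalanches(raster, rec)
  dens <- avalancheDensity(cat, rec, u0 = 2, stride = 0.37)
  ref <- bruteForceDensity(cat, rec, u0 = 2, stride = 0.37)
  s <- dens@series
  expect_equal(s$Fav, unname(ref[, "Fav"]))
  expect_equal(s$Nav, unname(ref[, "Nav"]))
  expect_equal(s$meanT, unname(ref[, "meanT"]))
  expect_equal(as.numeric(s$valid), unname(ref[, "valid"]))
})

test_that("density edge cases behave as defined", {
  rec <- randomZRec(2, 2000, seed = 22)
  empty <- extractAvalanches(detectExcursions(rec, 50), rec)
  dens <- avalancheDensity(empty, rec, u0 = 1, stride = 1)
  expect_true(all(dens@series$Fav == 0))
  ## an avalanche spanning an entire window gives Fav = 1 there
  sig <- matrix(0, 1, 1000)
  sig[1, 101:400] <- 3
  sig[1, 601:900] <- -3
  rec2 <- new("MultichannelRecording", signal = sig, fs = 100,
              channelLabels = "ch01", mask = rep(TRUE, 1000), t0 = 0,
              zscored = TRUE)
  cat2 <- extractAvalanches(detectExcursions(rec2, 2), rec2)
  dens2 <- avalancheDensity(cat2, rec2, u0 = 1, stride = 1 / 100)
  expect_equal(max(dens2@series$Fav), 1)
  expect_error(avalancheDensity(cat2, rec2, u0 = 0.001), "2 samples")
})

test_that("density over tiling windows conserves total avalanche time", {
  sur <- smallSurrogate()
  u0 <- 10
  dens <- avalancheDensity(sur$catalog, sur$rec, u0 = u0, stride = u0)
  s <- dens@series
  covered <- sum(s$Fav) * u0
  total <- sum(avalancheDurations(sur$catalog))
  ## agreement up to the partial window at the end of the recording
  expect_lt(abs(covered - total), u0)
})

test_that("stage density summary extracts per-stage means exactly", {
  ## constructed fixture: density 0.8 in N3 windows, 0.2 elsewhere
  stages <- rep(c("N2", "N3", "N2", "N3"), each = 5)
  hyp <- new("Hypnogram", epochStages = stages, epochLength = 30, startS = 0)
  t <- seq(5, totalDuration(hyp) - 5, by = 10)
  stageAt <- stages[floor(t / 30) + 1]
  series <- data.frame(t = t, Fav = ifelse(stageAt == "N3", 0.8, 0.2),
                       Nav = 1, meanT = 1, valid = TRUE)
  dens <- new("DensitySeries", series = series, u0 = 10, stride = 10)
  summ <- stageDensitySummary(dens, hyp)
  expect_equal(unname(summ$stageMeans["N3"]), 0.8)
  expect_equal(unname(summ$stageMeans["N2"]), 0.2)
  expect_true(is.na(summ$stageMeans["REM"]))
  ## identical first/last N3 densities: t statistic ~ 0
  expect_equal(summ$firstLastN3$firstMean, 0.8)
  expect_equal(summ$firstLastN3$lastMean, 0.8)
  ## no N3 at all: comparison absent
  hyp2 <- new("Hypnogram", epochStages = rep("N2", 20), epochLength = 30,
              startS = 0)
  summ2 <- stageDensitySummary(dens, hyp2)
  expect_true(is.na(summ2$stageMeans["N3"]))
  expect_null(summ2$firstLastN3)
})

test_that("first N3 density exceeds last when constructed to decay", {
  stages <- rep(c("N3", "N2", "N3"), each = 10)
  hyp <- new("Hypnogram", epochStages = stages, epochLength = 30, startS = 0)
  t <- seq(5, totalDuration(hyp) - 5, by = 10)
  stageAt <- stages[floor(t / 30) + 1]
  set.seed(23)
  Fav <- ifelse(stageAt == "N3" & t < 300, 0.8, 0.3) + rnorm(length(t), 0,
                                                             0.01)
  dens <- new("DensitySeries",
              series = data.frame(t = t, Fav = pmin(pmax(Fav, 0), 1), Nav = 1,
                                  meanT = 1, valid = TRUE),
              u0 = 10, stride = 10)
  summ <- stageDensitySummary(dens, hyp)
  expect_gt(summ$firstLastN3$firstMean, summ$firstLastN3$lastMean)
  expect_lt(summ$firstLastN3$p, 0.01)
})
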