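mkIndicator <- function(values, mask = rep(TRUE, length(values)),
                        name = "x") {
  new("BinaryIndicator", values = values & mask, featureName = name,
      mask = mask)
}

test_that("hypnogram IO round-trips and validates labels", {
  hyp <- new("Hypnogram", epochStages = rep(c("W", "N1", "N2", "N3", "REM"),
                                            2), epochLength = 30, startS = 0)
  expect_equal(totalDuration(hyp), 300)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeHypnogram(hyp, f)
  expect_identical(epochStages(readHypnogram(f)), epochStages(hyp))
  writeLines(c("epoch_index\tstage", "0\tN2", "1\tN4"), f)
  expect_error(readHypnogram(f), "N4")
})

test_that("CAP IO enforces overlap and warns on out-of-bounds durations", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("onset_s,duration_s,label", f)
  empty <- readCapAnnotations(f)
  expect_equal(nrow(capPhases(empty)), 0)
  writeLines(c("onset_s,duration_s,label", "0,70,A1", "80,10,B"), f)
  expect_warning(cap <- readCapAnnotations(f), "\\[2, 60\\]")
  expect_equal(nrow(capPhases(cap)), 2)
  writeLines(c("onset_s,duration_s,label", "0,10,A1", "5,10,B"), f)
  expect_error(readCapAnnotations(f), "overlap")
  ## generator output round-trips
  arch <- architectureConfig(nCycles = 2L)
  hyp <- simulateHypnogram(arch, seed = 1)
  cap2 <- simulateCapAnnotations(hyp, arch, seed = 2)
  writeCapAnnotations(cap2, f)
  back <- readCapAnnotations(f, hyp)
  expect_equal(capPhases(back), capPhases(cap2), tolerance = 1e-12)
})

test_that("indicators partition retained samples and compose correctly", {
  sur <- smallSurrogate()
  ind <- buildIndicators(sur$catalog, sur$hyp, sur$cap, sur$rec)
  mask <- retainedMask(sur$rec)
  stageUnion <- ind$W@values | ind$N1@values | ind$N2@values |
    ind$N3@values | ind$REM@values
  expect_identical(stageUnion, mask)
  expect_identical(ind$A@values,
                   ind$A1@values | ind$A2@values | ind$A3@values)
  nrem <- ind$N1@values | ind$N2@values | ind$N3@values
  expect_identical(ind$NCAP@values, nrem & !ind$CAP@values)
  ## CAP sequences live inside NREM only
  expect_true(all(!ind$CAP@values | nrem))
})

test_that("single-cycle annotations fail the sequence rule; the span is NCAP", {
  hyp <- new("Hypnogram", epochStages = rep("N2", 10), epochLength = 30,
             startS = 0)
  ph <- data.frame(onset_s = c(50, 60), duration_s = c(10, 20),
                   label = c("A1", "B"))
  cap <- new("CapAnnotation", phases = ph)
  sig <- matrix(0, 1, 300 * 100)
  rec <- new("MultichannelRecording", signal = sig, fs = 100,
             channelLabels = "ch01", mask = rep(TRUE, ncol(sig)), t0 = 0,
             zscored = TRUE)
  cat <- extractAvalanches(detectExcursions(rec, 2), rec)
  ## default rule needs >= 2 cycles: the lone A-B pair is NCAP
  ind <- buildIndicators(cat, hyp, cap, rec)
  expect_equal(sum(ind$CAP@values), 0)
  expect_equal(sum(ind$NCAP@values), 300 * 100)
  ## with minCycles = 1 the pair forms 30 s of CAP, 270 s NCAP
  ind1 <- buildIndicators(cat, hyp, cap, rec, minCycles = 1L)
  expect_equal(sum(ind1$CAP@values) / 100, 30)
  expect_equal(sum(ind1$NCAP@values) / 100, 270)
})

test_that("phi matches the 2x2 closed form and its symmetries", {
  x <- mkIndicator(rep(c(TRUE, FALSE), c(50, 50)))
  y <- mkIndicator(rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40)))
  ## n11=40 n10=10 n01=10 n00=40 -> phi = 0.6
  expect_equal(phiCorrelation(x, y), 0.6, tolerance = 1e-12)
  expect_equal(phiCorrelation(y, x), phiCorrelation(x, y))
  expect_equal(phiCorrelation(x, x), 1)
  notX <- mkIndicator(!x@values)
  expect_equal(phiCorrelation(x, notX), -1)
  expect_equal(phiCorrelation(notX, y), -phiCorrelation(x, y),
               tolerance = 1e-12)
  expect_error(phiCorrelation(x, mkIndicator(rep(TRUE, 100))), "constant")
})

test_that("occupancy fraction is a conditional coverage", {
  a <- mkIndicator(rep(c(TRUE, FALSE), c(42, 58)))
  b <- mkIndicator(rep(c(TRUE, FALSE), c(100, 0)))
  expect_equal(occupancyFraction(a, b), 0.42)
  expect_equal(occupancyFraction(b, b), 1)
  disj <- mkIndicator(rep(c(FALSE, TRUE), c(42, 58)))
  expect_equal(occupancyFraction(a, disj), 0)
  none <- mkIndicator(rep(FALSE, 100))
  expect_error(occupancyFraction(a, none), "positive")
})

test_that("CAP metrics reproduce a hand-built annotation", {
  hyp <- new("Hypnogram", epochStages = rep("N2", 10), epochLength = 30,
             startS = 0)
  ## 5 contiguous A-B cycles of 30 s each -> one 150 s sequence in 300 s NREM
  on <- seq(0, by = 30, length.out = 5)
  ph <- data.frame(onset_s = sort(c(on, on + 10)),
                   duration_s = rep(c(10, 20), 5),
                   label = rep(c("A1", "B"), 5))
  cap <- new("CapAnnotation", phases = ph)
  m <- capMetrics(cap, hyp)
  expect_equal(m$capRate, 0.5)
  expect_equal(m$capTimeMin, 2.5)
  expect_equal(m$nSequences, 1L)
  expect_equal(m$totalCycles, 5L)
  expect_equal(m$meanPhaseALength, 10)
  expect_equal(m$meanPhaseBLength, 20)
  expect_equal(m$subtypes$A1$timeShareOfCAP, 50 / 150)
  noCap <- new("CapAnnotation",
               phases = data.frame(onset_s = numeric(0),
                                   duration_s = numeric(0),
                                   label = character(0)))
  expect_equal(capMetrics(noCap, hyp)$capRate, 0)
  wake <- new("Hypnogram", epochStages = rep("W", 4), epochLength = 30,
              startS = 0)
  expect_error(capMetrics(cap, wake), "NREM")
})

test_that("group comparison reproduces hand-computed statistics", {
  res <- groupComparison(list(a = c(1, 2, 3), b = c(2, 3, 4),
                              c = c(3, 4, 5)))
  expect_equal(res$method, "one-way ANOVA")
  expect_equal(res$statistic, 3)           # SSB = 6 (df 2), SSW = 6 (df 6)
  same <- groupComparison(list(a = c(1, 2, 3), b = c(1, 2, 3),
                               c = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  ## non-normal groups route through Kruskal-Wallis; the H statistic is
  ## checked against the brute-force rank-sum formula
  g <- list(a = c(0.1, 0.2, 0.3, 0.4, 50), b = c(0.5, 0.6, 0.7, 0.8, 60),
            c = c(0.9, 1.1, 1.2, 1.3, 70))
  skewed <- groupComparison(g)
  expect_equal(skewed$method, "Kruskal-Wallis")
  rk <- rank(unlist(g))
  rs <- tapply(rk, rep(names(g), lengths(g)), sum)
  N <- length(rk)
  H <- 12 / (N * (N + 1)) * sum(rs^2 / lengths(g)) - 3 * (N + 1)
  expect_equal(unname(skewed$statistic), H, tolerance = 1e-9)
  expect_error(groupComparison(list(a = 1:2, b = 1:3)), "at least 3")
  ## paired two-group design
  pr <- groupComparison(list(a = c(1, 2, 3, 4), b = c(1.4, 2.5, 3.6, 4.5)),
                        paired = TRUE)
  expect_equal(pr$method, "paired t")
  expect_lt(pr$p, 0.05)
})
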