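test_that("unbounded MLE reduces to the Hill closed form", {
  ## sample constructed so mean log(x/xmin) = 1 exactly -> gamma = 2
  x <- exp(c(rep(0.5, 10), rep(1.5, 10)))
  fit <- fitPowerLawMLE(x, xmin = 1, xmax = Inf)
  expect_equal(fit@exponent, 2, tolerance = 1e-12)
  set.seed(1)
  y <- samplePowerLaw(1.8, 2, Inf, 5000)
  hill <- 1 + length(y) / sum(log(y / 2))
  expect_equal(fitPowerLawMLE(y, 2, Inf)@exponent, hill, tolerance = 1e-12)
})

test_that("truncated MLE recovers the generating exponent", {
  x <- samplePowerLaw(1.5, 1, 1000, 100000, seed = 2)
  fit <- fitPowerLawMLE(x, 1, 1000)
  expect_lt(abs(fit@exponent - 1.5), 0.01)
  expect_error(fitPowerLawMLE(x[1:5], 1, 1000), "at least 10")
  expect_error(fitPowerLawMLE(x, 10, 5), "exceed")
})

test_that("exponent recovery has small bias and spread at large n", {
  for (gamma in c(1.5, 2.0)) {
    est <- vapply(1:5, function(i) {
      x <- samplePowerLaw(gamma, 1, 1000, 100000, seed = 1000 * gamma + i)
      fitPowerLawMLE(x, 1, 1000)@exponent
    }, numeric(1))
    expect_lt(abs(mean(est) - gamma), 0.02)
    expect_lt(sd(est), 0.02)
  }
})

test_that("optimizer agrees with a dense grid search of the likelihood", {
  x <- samplePowerLaw(1.5, 1, 1000, 20000, seed = 3)
  fit <- fitPowerLawMLE(x, 1, 1000)
  grid <- seq(1.01, 3, by = 1e-5)
  tail <- x[x >= 1 & x <= 1000]
  sl <- sum(log(tail)); n <- length(tail)
  ll <- vapply(grid, function(g)
    n * sleepAvalanche:::.plLogC(g, 1, 1000) - g * sl, numeric(1))
  expect_lt(abs(fit@exponent - grid[which.max(ll)]), 1e-4)
})

test_that("fitted truncated density integrates to one", {
  x <- samplePowerLaw(1.7, 2, 500, 5000, seed = 4)
  fit <- fitPowerLawMLE(x, 2, 500)
  dens <- function(v) exp(sleepAvalanche:::.plLogC(fit@exponent, 2, 500)) *
    v^(-fit@exponent)
  expect_equal(integrate(dens, 2, 500, rel.tol = 1e-12)$value, 1,
               tolerance = 1e-9)
})

test_that("KS distance handles jumps, converges, and matches a dense grid", {
  ## single sample at the fitted median jumps across F = 0.5
  fit <- new("PowerLawFit", exponent = 2, xmin = 1, xmax = 100, nTail = 10L,
             ksD = 0, loglik = 0)
  med <- 1 / (1 - 0.5 * (1 - 1 / 100))  # F(med) = 0.5 for gamma = 2
  expect_equal(ksDistance(med, fit), 0.5)
  ## D shrinks for samples drawn from the fitted law
  x <- samplePowerLaw(2, 1, 100, 10000, seed = 5)
  bigFit <- fitPowerLawMLE(x, 1, 100)
  expect_lt(bigFit@ksD, 0.02)
  ## jump-point supremum equals a brute-force grid evaluation
  xs <- sort(samplePowerLaw(1.6, 1, 50, 500, seed = 6))
  f2 <- fitPowerLawMLE(xs, 1, 50)
  grid <- exp(seq(log(1), log(50), length.out = 100000))
  Femp <- ecdf(xs)
  brute <- max(abs(Femp(grid) - powerLawCDF(grid, f2@exponent, 1, 50)))
  expect_lt(abs(ksDistance(xs, f2) - brute), 1e-3)
})

test_that("KS distance is invariant under common rescaling", {
  x <- samplePowerLaw(1.8, 1, 100, 2000, seed = 7)
  fit <- fitPowerLawMLE(x, 1, 100)
  fitScaled <- new("PowerLawFit", exponent = fit@exponent, xmin = 10,
                   xmax = 1000, nTail = fit@nTail, ksD = 0, loglik = 0)
  expect_equal(ksDistance(x, fit), ksDistance(10 * x, fitScaled),
               tolerance = 1e-12)
})

test_that("log-likelihood ratio separates power-law from exponential data", {
  set.seed(8)
  xe <- 1 + rexp(10000, 2)
  xe <- xe[xe <= 20]
  cmpE <- comparePowerLawExponential(xe, 1, 20)
  expect_lt(cmpE$R, 0)
  expect_lt(cmpE$p, 0.05)
  xp <- samplePowerLaw(1.5, 1, 1000, 10000, seed = 9)
  cmpP <- comparePowerLawExponential(xp, 1, 1000)
  expect_gt(cmpP$R, 0)
  expect_lt(cmpP$p, 0.05)
  expect_error(comparePowerLawExponential(rep(2, 100), 1, 10), "degenerate")
})

test_that("systematic-error grid has the specified shape and behavior", {
  x <- samplePowerLaw(1.5, 0.4, 1200, 50000, seed = 10)
  grid <- systematicErrorGrid(x, c(0.5, 1, 2, 3, 4), 550, 1000, 10L,
                              seed = 11)
  expect_equal(dim(grid$exponentMatrix), c(5L, 10L))
  expect_equal(sum(!is.na(grid$exponentMatrix)), 50)
  expect_lt(abs(grid$meanExponent - 1.5), 2 * max(grid$sdExponent, 0.01))
  single <- systematicErrorGrid(x, 1, 800, 800, 1L, seed = 12)
  expect_equal(single$sdExponent, 0)
})

test_that("scaling fit is exact on log-linear data and finds both regimes", {
  ## one distinct duration per bin -> slopes are exact
  Td <- exp(seq(log(0.02), log(4), length.out = 24))
  s <- 4 * Td^2
  fit <- sizeDurationScaling(Td, sizes = s, tMin = 0.01, tMax = 5,
                             nBins = 30L, splitT = 0.4)
  expect_equal(fit@kLow, 2, tolerance = 1e-9)
  expect_equal(fit@kHigh, 2, tolerance = 1e-9)
  ## piecewise slopes (2 then 1.3, crossover 0.4) recovered within 0.05
  sPiece <- ifelse(Td < 0.4, 5 * Td^2, 5 * 0.4^(2 - 1.3) * Td^1.3)
  fit2 <- sizeDurationScaling(Td, sizes = sPiece, tMin = 0.01, tMax = 5,
                              nBins = 30L, splitT = 0.4)
  expect_lt(abs(fit2@kLow - 2), 0.05)
  expect_lt(abs(fit2@kHigh - 1.3), 0.05)
  ## a regime with too few bins is reported missing
  fit3 <- sizeDurationScaling(Td[Td < 0.3], sizes = s[Td < 0.3], tMin = 0.01,
                              tMax = 5, nBins = 30L, splitT = 0.4)
  expect_true(is.na(fit3@kHigh))
})

test_that("scaling relation arithmetic and propagation are correct", {
  expect_equal(checkScalingRelation(1.5, 2, 2)$predictedK, 2)
  expect_equal(checkScalingRelation(2, 3, 2)$predictedK, 2)
  expect_equal(round(checkScalingRelation(1.45, 1.96, 1.96)$predictedK, 2),
               2.13)
  expect_error(checkScalingRelation(1, 2, 2), "tau")
  rep <- checkScalingRelation(1.5, 2, 2.05, tauErr = 0.03, alphaErr = 0.05,
                              kErr = 0.04)
  expect_true(rep$consistent)
  expect_equal(rep$predictedKErr,
               sqrt((0.05 / 0.5)^2 + (1 * 0.03 / 0.25)^2), tolerance = 1e-12)
})
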